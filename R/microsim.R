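# Individual-level Monte Carlo microsimulation with the identical monthly
# event logic as the deterministic cohort engine. Serves as a stochastic
# oracle for the engine and as the synthetic-trajectory generator: the model's
# stated hazards ARE the data-generating process.
#
# Random number layout: a single stream seeded once; patient i consumes the
# i-th contiguous block of 1 + 3*cycles uniforms (initial state, then per
# cycle: hospitalization, death, test). Growing n therefore appends patients
# without reshuffling existing ones. When an efficacy scenario is supplied,
# the telehealth arm reuses the same uniforms as usual care (common random
# numbers), so the averted-admission subpopulation is well defined:
# an "exacerbation" is a hospitalization event under the usual-care hazard
# draw, and the telehealth arm admits only when the same draw also clears the
# reduced hazard.

#' Simulate individual patient trajectories
#'
#' Draws `n_patients` independent patients from the cohort's initial
#' distribution and simulates them cycle by cycle under usual care and — when
#' `eff` is supplied — under telehealth with common random numbers, accruing
#' the same discounted cost components as the deterministic economic layer.
#'
#' @param cohort A `chf_cohort`.
#' @param tp Usual-care `chf_transitions`.
#' @param eff A `chf_efficacy`, or `NULL` for a usual-care-only run.
#' @param costs A `chf_costs`.
#' @param n_patients Number of simulated patients.
#' @param cycles Number of monthly cycles.
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param settings Model conventions, see [chf_defaults()]`$settings`.
#' @param keep_trajectories If `TRUE`, also return a per patient-cycle tibble
#'   (intended for small `n_patients`).
#' @return An object of class `chf_microsim`: a list with
#'   \describe{
#'     \item{summary}{tibble with one row per arm (plus an `incremental` row
#'       for paired telehealth-minus-usual differences): means and Monte Carlo
#'       standard errors of discounted cost, life years and admissions.}
#'     \item{detection}{for telehealth runs, empirical true-positive rate
#'       among exacerbation cycles and false-positive rate among alive
#'       non-exacerbation cycles.}
#'     \item{occupancy_usual}{empirical state-occupancy fractions of the
#'       usual-care arm, one row per cycle 0..`cycles`.}
#'     \item{trajectories}{optional long tibble (`patient`, `cycle`, `arm`,
#'       `state`, `hospitalized`, `died`, `test`).}
#'   }
#' @export
simulate_cohort <- function(cohort, tp, eff = NULL, costs = cost_schedule(),
                            n_patients = 10000,
                            cycles = cohort$horizon_months,
                            seed = 1L,
                            settings = default_settings(),
                            keep_trajectories = FALSE) {
  stopifnot(inherits(cohort, "chf_cohort"), inherits(tp, "chf_transitions"))
  if (n_patients < 1) {
    rlang::abort("`n_patients` must be >= 1", class = "chfmarkov_argument_error")
  }
  settings <- validate_settings(settings)
  n <- as.integer(n_patients)
  cycles <- as.integer(cycles)
  tele <- !is.null(eff)
  if (tele) stopifnot(inherits(eff, "chf_efficacy"))

  set.seed(as.integer(seed))
  U <- matrix(stats::runif(n * (1L + 3L * cycles)),
              nrow = 1L + 3L * cycles, ncol = n)

  cum <- cumsum(cohort$initial_distribution)
  state_u <- findInterval(U[1L, ], cum) + 1L  # 1..6; 6 = death
  state_t <- state_u

  ph <- unname(tp$p_hosp_by_state)
  pdh <- tp$p_death_hospitalized
  pdn <- tp$p_death_not_hospitalized
  if (tele) {
    tpa <- adjust_hazards(tp, eff)
    pha <- unname(tpa$p_hosp_by_state)
    pdha <- tpa$p_death_hospitalized
    pdna <- tpa$p_death_not_hospitalized
    los_mult_tp <- 1 - eff$los_reduction  # multiplier for detected admissions
  }

  fixed_month <- (costs$annual_chf_outpatient + costs$annual_non_chf) / 12
  fee_month <- monthly_test_cost(costs)
  treat_fee <- treat_cost_per_episode(costs)
  df <- discount_factor(seq_len(cycles), costs$annual_discount_rate,
                        method = settings$discount_method)
  ly_df <- if (settings$discount_life_years) {
    discount_factor(seq_len(cycles), costs$annual_discount_rate)
  } else {
    rep(1, cycles)
  }

  cost_u <- cost_t <- numeric(n)
  ly_u <- ly_t <- numeric(n)
  adm_u <- adm_t <- numeric(n)
  occ_u <- matrix(0, nrow = cycles + 1L, ncol = 6L,
                  dimnames = list(NULL, chf_states()))
  occ_u[1L, ] <- tabulate(state_u, nbins = 6L) / n
  n_exac <- n_tp <- n_nonexac <- n_fp <- 0L
  traj <- if (keep_trajectories) vector("list", cycles) else NULL

  hazard_at <- function(state, alive, hz) {
    p <- numeric(length(state))
    p[alive] <- hz[state[alive]]
    p
  }
  exposure <- function(alive_start, died) {
    if (settings$half_cycle) alive_start * (1 - 0.5 * died) else alive_start
  }
  ly_exposure <- function(alive_start, died) {
    switch(settings$ly_convention,
           start = as.numeric(alive_start),
           end = as.numeric(alive_start & !died),
           half = alive_start * (1 - 0.5 * died))
  }

  for (t in seq_len(cycles)) {
    r <- 1L + 3L * (t - 1L)
    u <- U[r + 1L, ]
    w <- U[r + 2L, ]
    v <- U[r + 3L, ]

    # usual-care arm
    alive <- state_u < 6L
    hosp <- alive & (u < hazard_at(state_u, alive, ph))
    died <- (hosp & (w < pdh)) | (alive & !hosp & (w < pdn))
    expo <- exposure(alive, died)
    cost_u <- cost_u + df[t] * (expo * fixed_month +
                                  hosp * costs$cost_per_admission)
    ly_u <- ly_u + ly_df[t] * ly_exposure(alive, died) / 12
    adm_u <- adm_u + hosp
    state_u[hosp & !died] <- pmin(state_u[hosp & !died] + 1L, 5L)
    state_u[died] <- 6L
    occ_u[t + 1L, ] <- tabulate(state_u, nbins = 6L) / n
    if (keep_trajectories) {
      traj_u <- tibble::tibble(patient = seq_len(n), cycle = t, arm = "usual",
                               state = chf_states()[state_u],
                               hospitalized = hosp, died = died,
                               test = NA_character_)
    }

    # telehealth arm (common random numbers)
    if (tele) {
      alive2 <- state_t < 6L
      detected <- v < eff$sensitivity  # the test draw mediates the benefit
      exac <- alive2 & (u < hazard_at(state_t, alive2, ph))
      if (settings$efficacy_gating == "sen") {
        # only detected exacerbations receive the hazard reductions
        hosp2 <- exac & (detected & (u < hazard_at(state_t, alive2, pha)) | !detected)
        died2 <- (hosp2 & (w < ifelse(detected, pdha, pdh))) |
          (alive2 & !hosp2 & (w < ifelse(detected, pdna, pdn)))
      } else {
        hosp2 <- alive2 & (u < hazard_at(state_t, alive2, pha))
        died2 <- (hosp2 & (w < pdha)) | (alive2 & !hosp2 & (w < pdna))
      }
      positive <- (exac & detected) | (alive2 & !exac & (v < 1 - eff$specificity))
      detected_adm <- hosp2 & detected
      adm_mult <- if (settings$los_gating == "all") {
        ifelse(hosp2, los_mult_tp, 0)
      } else {
        ifelse(detected_adm, los_mult_tp, as.numeric(hosp2))
      }
      expo2 <- exposure(alive2, died2)
      cost_t <- cost_t + df[t] * (
        expo2 * (fixed_month + fee_month) +
          positive * treat_fee +
          adm_mult * costs$cost_per_admission
      )
      ly_t <- ly_t + ly_df[t] * ly_exposure(alive2, died2) / 12
      adm_t <- adm_t + hosp2
      n_exac <- n_exac + sum(exac)
      n_tp <- n_tp + sum(exac & (v < eff$sensitivity))
      n_nonexac <- n_nonexac + sum(alive2 & !exac)
      n_fp <- n_fp + sum(alive2 & !exac & (v < 1 - eff$specificity))
      state_t[hosp2 & !died2] <- pmin(state_t[hosp2 & !died2] + 1L, 5L)
      state_t[died2] <- 6L
      if (keep_trajectories) {
        traj[[t]] <- dplyr::bind_rows(
          traj_u,
          tibble::tibble(patient = seq_len(n), cycle = t, arm = "telehealth",
                         state = chf_states()[state_t],
                         hospitalized = hosp2, died = died2,
                         test = dplyr::case_when(
                           !alive2 ~ NA_character_,
                           exac & positive ~ "TP",
                           exac & !positive ~ "FN",
                           positive ~ "FP",
                           TRUE ~ "TN"
                         ))
        )
      }
    } else if (keep_trajectories) {
      traj[[t]] <- traj_u
    }
  }

  summarize_arm <- function(arm, cost, ly, adm) {
    tibble::tibble(
      arm = arm, n = n,
      mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
      mean_life_years = mean(ly), se_life_years = stats::sd(ly) / sqrt(n),
      mean_admissions = mean(adm), se_admissions = stats::sd(adm) / sqrt(n)
    )
  }
  summary <- summarize_arm("usual", cost_u, ly_u, adm_u)
  detection <- NULL
  if (tele) {
    summary <- dplyr::bind_rows(
      summary,
      summarize_arm("telehealth", cost_t, ly_t, adm_t),
      summarize_arm("incremental", cost_t - cost_u, ly_t - ly_u, adm_t - adm_u)
    )
    detection <- list(
      tp_rate = if (n_exac > 0) n_tp / n_exac else NA_real_,
      fp_rate = if (n_nonexac > 0) n_fp / n_nonexac else NA_real_,
      n_exacerbation_cycles = n_exac,
      n_nonexacerbation_cycles = n_nonexac
    )
  }
  structure(
    list(
      summary = summary,
      detection = detection,
      occupancy_usual = occ_u,
      trajectories = if (keep_trajectories) dplyr::bind_rows(traj) else NULL,
      cohort_label = cohort$label,
      cycles = cycles,
      seed = as.integer(seed)
    ),
    class = "chf_microsim"
  )
}

#' @export
print.chf_microsim <- function(x, ...) {
  cat(sprintf("<chf_microsim> cohort %s, %d cycles, n = %d, seed %d\n",
              x$cohort_label, x$cycles, x$summary$n[1], x$seed))
  print(x$summary)
  invisible(x)
}

#' Tidy a microsimulation
#'
#' @param x A `chf_microsim`.
#' @param ... Unused.
#' @return The per-arm summary tibble.
#' @export
tidy.chf_microsim <- function(x, ...) x$summary
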