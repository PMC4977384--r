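# Deterministic monthly state-transition propagation of cohort probability
# mass through the 6-state model.
#
# Event ordering within a cycle: hospitalization is resolved first; death is
# then conditional on hospitalization status. Survivors of a hospitalization
# advance one admission state (H4plus is a ceiling); non-hospitalized
# survivors remain in place. There is no recovery to a lower state.

#' Detection-gated effective efficacy
#'
#' Under the default `efficacy_gating = "sen"` convention, the clinical
#' benefit of telehealth reaches only the exacerbations the monitoring TEST
#' detects: a missed diagnosis leaves the patient on the usual-care hazards.
#' The population-level mortality and hospitalization reductions are therefore
#' the scenario values scaled by the detection sensitivity. With
#' `gating = "none"` the scenario reductions apply to everyone unchanged.
#'
#' @param eff A `chf_efficacy` object.
#' @param gating `"sen"` (scale reductions by sensitivity) or `"none"`.
#' @return A `chf_efficacy` object with the effective reductions.
#' @export
effective_efficacy <- function(eff, gating = c("sen", "none")) {
  gating <- match.arg(gating)
  if (gating == "none") return(eff)
  efficacy_scenario(
    sensitivity = eff$sensitivity,
    specificity = eff$specificity,
    mortality_reduction = eff$mortality_reduction * eff$sensitivity,
    hospitalization_reduction = eff$hospitalization_reduction * eff$sensitivity,
    los_reduction = eff$los_reduction,
    label = paste0(eff$label, " (detection-gated)")
  )
}

#' Apply telehealth efficacy to usual-care hazards
#'
#' Multiplies each state's hospitalization probability by
#' `1 - hospitalization_reduction` and both death probabilities by
#' `1 - mortality_reduction`. Sensitivity, specificity and the LOS reduction
#' act only on costs, never on hazards.
#'
#' @param base A `chf_transitions` object (usual care).
#' @param eff A `chf_efficacy` object.
#' @return A `chf_transitions` object with adjusted hazards.
#' @export
adjust_hazards <- function(base, eff) {
  stopifnot(inherits(base, "chf_transitions"), inherits(eff, "chf_efficacy"))
  transition_parameters(
    p_hosp_by_state = base$p_hosp_by_state * (1 - eff$hospitalization_reduction),
    p_death_not_hospitalized = base$p_death_not_hospitalized * (1 - eff$mortality_reduction),
    p_death_hospitalized = base$p_death_hospitalized * (1 - eff$mortality_reduction),
    label = paste0(base$label, " + ", eff$label)
  )
}

#' One-cycle transition matrix
#'
#' Row-stochastic 6x6 matrix implied by a hazard set; rows index the state at
#' cycle start, columns the state at cycle end.
#'
#' @param tp A `chf_transitions` object.
#' @return A 6x6 matrix with dimnames [chf_states()].
#' @export
transition_matrix <- function(tp) {
  states <- chf_states()
  P <- matrix(0, 6, 6, dimnames = list(states, states))
  ph <- tp$p_hosp_by_state
  pdh <- tp$p_death_hospitalized
  pdn <- tp$p_death_not_hospitalized
  for (i in 1:5) {
    stay <- (1 - ph[i]) * (1 - pdn)
    advance <- ph[i] * (1 - pdh)
    die <- ph[i] * pdh + (1 - ph[i]) * pdn
    j <- min(i + 1, 5)
    P[i, i] <- P[i, i] + stay
    P[i, j] <- P[i, j] + advance
    P[i, 6] <- die
  }
  P[6, 6] <- 1
  P
}

#' Advance a cohort state vector by one monthly cycle
#'
#' @param state Named numeric vector of probability mass over [chf_states()].
#' @param tp A `chf_transitions` object.
#' @return A list with `state` (end-of-cycle mass), `expected_admissions`
#'   (expected hospitalization events per initial patient during the cycle)
#'   and `expected_deaths`.
#' @export
step_cycle <- function(state, tp) {
  stopifnot(length(state) == 6L, all(state >= 0))
  living <- state[1:5]
  ph <- tp$p_hosp_by_state
  admissions <- sum(living * ph)
  deaths <- sum(living * (ph * tp$p_death_hospitalized +
                          (1 - ph) * tp$p_death_not_hospitalized))
  new_state <- as.numeric(state %*% transition_matrix(tp))
  names(new_state) <- chf_states()
  list(state = new_state, expected_admissions = admissions, expected_deaths = deaths)
}

#' Propagate a cohort over a horizon
#'
#' Iterates [step_cycle()] from the cohort's initial distribution and records a
#' per-cycle trace. Row `cycle = 0` holds the initial occupancy; row `cycle = t`
#' holds the occupancy at the end of cycle `t`, the fraction alive at the start
#' of cycle `t`, and the expected admissions and deaths during cycle `t`.
#'
#' @param cohort A `chf_cohort` object.
#' @param tp A `chf_transitions` object.
#' @param cycles Number of monthly cycles (default: the cohort's horizon).
#' @return A tibble of class `chf_trace` with columns `cycle`, one column per
#'   state, `alive_at_start`, `expected_admissions`, `expected_deaths`.
#' @export
run_horizon <- function(cohort, tp, cycles = cohort$horizon_months) {
  stopifnot(inherits(cohort, "chf_cohort"), inherits(tp, "chf_transitions"))
  if (!is.numeric(cycles) || length(cycles) != 1L || is.na(cycles) || cycles < 1) {
    rlang::abort("`cycles` must be a positive integer",
                 class = "chfmarkov_argument_error")
  }
  cycles <- as.integer(cycles)
  states <- chf_states()
  occ <- matrix(NA_real_, nrow = cycles + 1L, ncol = 6L,
                dimnames = list(NULL, states))
  occ[1, ] <- cohort$initial_distribution
  adm <- dth <- numeric(cycles + 1L)
  state <- cohort$initial_distribution
  for (t in seq_len(cycles)) {
    stepped <- step_cycle(state, tp)
    state <- stepped$state
    occ[t + 1L, ] <- state
    adm[t + 1L] <- stepped$expected_admissions
    dth[t + 1L] <- stepped$expected_deaths
  }
  out <- tibble::as_tibble(as.data.frame(occ))
  out <- dplyr::mutate(
    out,
    cycle = 0:cycles,
    alive_at_start = c(NA_real_, 1 - occ[seq_len(cycles), "death"]),
    expected_admissions = adm,
    expected_deaths = dth,
    .before = 1
  )
  out <- out[, c("cycle", states, "alive_at_start",
                 "expected_admissions", "expected_deaths")]
  structure(out,
            class = c("chf_trace", class(out)),
            cohort_label = cohort$label,
            transitions_label = tp$label,
            cycles = cycles)
}

# Per-cycle alive exposure (cycles 1..T): "start" credits a full month to
# patients alive at cycle start, "end" only to those who survive the cycle,
# "half" the half-cycle-corrected average of the two.
alive_measure <- function(trace, convention = c("start", "end", "half")) {
  convention <- match.arg(convention)
  alive <- 1 - trace$death
  start <- alive[-nrow(trace)]
  end <- alive[-1]
  switch(convention, start = start, end = end, half = (start + end) / 2)
}

# Cost-accrual exposure follows the half_cycle flag only.
cost_exposure <- function(trace, half_cycle = FALSE) {
  alive_measure(trace, if (half_cycle) "half" else "start")
}

#' Life years lived by a cohort
#'
#' Sum over cycles of the alive fraction, in years; the study's health outcome
#' carries no utility weighting. Undiscounted with start-of-cycle person-time
#' by default; the full analyses use the conventions in
#' [chf_defaults()]`$settings` (end-of-cycle survival, discounted at the cost
#' schedule's rate with monthly granularity).
#'
#' @param trace A `chf_trace` from [run_horizon()].
#' @param convention Person-time credit per cycle: `"start"` (alive at cycle
#'   start), `"end"` (survived the cycle), or `"half"` (average of the two).
#' @param discount_rate Annual discount rate applied to life years
#'   (0 = undiscounted).
#' @return Life years per initial patient.
#' @export
life_years <- function(trace, convention = "start", discount_rate = 0) {
  alive <- alive_measure(trace, convention)
  df <- discount_factor(seq_along(alive), discount_rate)
  sum(alive * df) / 12
}

#' Total expected admissions in a trace
#'
#' @param trace A `chf_trace`.
#' @return Expected hospitalization events per initial patient (undiscounted).
#' @export
total_admissions <- function(trace) sum(trace$expected_admissions)

#' @export
print.chf_trace <- function(x, ...) {
  cat(sprintf("<chf_trace> cohort %s, %s, %d cycles\n",
              attr(x, "cohort_label"), attr(x, "transitions_label"),
              attr(x, "cycles")))
  NextMethod()
}
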