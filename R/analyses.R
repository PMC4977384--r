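# Orchestration of the study's experiments: arm comparisons, one- and two-way
# sensitivity analyses, break-even fee solving, and validation runs.

#' Compare telehealth against usual care for one cohort
#'
#' Runs the cohort engine and the economic layer for both arms from identical
#' initial conditions and returns absolute usual-care outcomes together with
#' telehealth increments (telehealth minus usual care; negative incremental
#' cost denotes a saving).
#'
#' @param cohort A `chf_cohort` object.
#' @param scenario A `chf_efficacy` object.
#' @param costs A `chf_costs` object.
#' @param tp Usual-care `chf_transitions`.
#' @param horizon_months Number of monthly cycles.
#' @param settings Model conventions, see [chf_defaults()]`$settings`.
#' @return An object of class `chf_comparison`; see [tidy()][generics::tidy]
#'   and [glance()][generics::glance] methods.
#' @export
compare_arms <- function(cohort, scenario, costs, tp,
                         horizon_months = cohort$horizon_months,
                         settings = default_settings()) {
  settings <- validate_settings(settings)
  ly_rate <- if (settings$discount_life_years) costs$annual_discount_rate else 0

  trace_u <- run_horizon(cohort, tp, cycles = horizon_months)
  tp_adj <- adjust_hazards(tp, effective_efficacy(scenario, settings$efficacy_gating))
  trace_t <- run_horizon(cohort, tp_adj, cycles = horizon_months)

  cost_u <- accumulate_costs(trace_u, "usual", tp, scenario, costs, settings)
  cost_t <- accumulate_costs(trace_t, "telehealth", tp, scenario, costs, settings)

  arm_summary <- function(trace, cost_trace) {
    list(
      cost = cost_total(cost_trace),
      life_years = life_years(trace, convention = settings$ly_convention,
                              discount_rate = ly_rate),
      admissions = total_admissions(trace)
    )
  }
  usual <- arm_summary(trace_u, cost_u)
  tele <- arm_summary(trace_t, cost_t)
  structure(
    list(
      cohort_label = cohort$label,
      scenario_label = scenario$label,
      horizon_months = as.integer(horizon_months),
      usual = usual,
      telehealth = tele,
      incremental = list(
        cost = tele$cost - usual$cost,
        life_years = tele$life_years - usual$life_years,
        admissions = tele$admissions - usual$admissions
      ),
      cost_traces = list(usual = cost_u, telehealth = cost_t),
      traces = list(usual = trace_u, telehealth = trace_t),
      settings = settings
    ),
    class = "chf_comparison"
  )
}

#' @export
print.chf_comparison <- function(x, ...) {
  cat(sprintf("<chf_comparison> cohort %s, scenario %s, %d months\n",
              x$cohort_label, x$scenario_label, x$horizon_months))
  cat(sprintf("  usual care:  cost $%.0f, %.2f LY, %.2f admissions\n",
              x$usual$cost, x$usual$life_years, x$usual$admissions))
  d <- x$incremental
  saving <- if (d$cost < 0) sprintf(" (saving $%.0f)", -d$cost) else ""
  cat(sprintf("  telehealth increment: %+.0f USD%s, %+.3f LY, %+.3f admissions\n",
              d$cost, saving, d$life_years, d$admissions))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an arm comparison
#'
#' One row per arm plus an `incremental` row (telehealth minus usual care).
#'
#' @param x A `chf_comparison`.
#' @param ... Unused.
#' @return A tibble with columns `cohort`, `scenario`, `horizon_months`,
#'   `arm`, `cost`, `life_years`, `admissions`.
#' @export
tidy.chf_comparison <- function(x, ...) {
  rows <- list(usual = x$usual, telehealth = x$telehealth,
               incremental = x$incremental)
  purrr::imap_dfr(rows, function(r, arm) {
    tibble::tibble(
      cohort = x$cohort_label,
      scenario = x$scenario_label,
      horizon_months = x$horizon_months,
      arm = arm,
      cost = r$cost,
      life_years = r$life_years,
      admissions = r$admissions
    )
  })
}

#' Glance at an arm comparison
#'
#' @param x A `chf_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with usual-care outcomes and the telehealth
#'   increments (`d_cost`, `d_life_years`, `d_admissions`).
#' @export
glance.chf_comparison <- function(x, ...) {
  tibble::tibble(
    cohort = x$cohort_label,
    scenario = x$scenario_label,
    horizon_months = x$horizon_months,
    usual_cost = x$usual$cost,
    usual_life_years = x$usual$life_years,
    usual_admissions = x$usual$admissions,
    d_cost = x$incremental$cost,
    d_life_years = x$incremental$life_years,
    d_admissions = x$incremental$admissions
  )
}

#' Base-case results table
#'
#' Runs [compare_arms()] for every cohort x horizon combination and returns
#' the glance rows — one row per cohort and horizon, with usual-care outcomes
#' and telehealth increments (cumulative totals at each horizon).
#'
#' @param config A `chf_config` bundle (default: built-in).
#' @param cohorts Character vector of cohort labels from the bundle.
#' @param horizons Horizons in months.
#' @param scenario_label Efficacy scenario label from the bundle.
#' @return A tibble, one row per cohort x horizon.
#' @export
basecase_table <- function(config = chf_defaults(),
                           cohorts = names(config$cohorts),
                           horizons = c(12, 36, 60),
                           scenario_label = "base") {
  check_labels(cohorts, names(config$cohorts), "cohort")
  check_labels(scenario_label, names(config$scenarios), "scenario")
  scen <- config$scenarios[[scenario_label]]
  tidyr::expand_grid(cohort = cohorts, horizon_months = horizons) |>
    purrr::pmap_dfr(function(cohort, horizon_months) {
      co <- config$cohorts[[cohort]]
      glance(compare_arms(co, scen, config$costs,
                          config$transitions[[co$nyha_label]],
                          horizon_months = horizon_months,
                          settings = config$settings))
    })
}

check_labels <- function(x, valid, what) {
  bad <- setdiff(x, valid)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown %s label '%s'; valid labels: %s",
                         what, bad[1], paste(valid, collapse = ", ")),
                 class = "chfmarkov_argument_error")
  }
  invisible(x)
}

#' One-way sensitivity sweep over an efficacy parameter
#'
#' Scales one of the three reduction parameters (mortality, hospitalization,
#' LOS) by each factor in `scale_grid` while holding the other efficacy
#' parameters at the scenario values, and records the incremental cost.
#'
#' @param cohort A `chf_cohort`.
#' @param costs A `chf_costs`.
#' @param tp Usual-care `chf_transitions`.
#' @param horizon_months Horizon in months.
#' @param which Which reduction to scale: `"mortality"`, `"hospitalization"`
#'   or `"los"`.
#' @param scale_grid Multiplicative factors applied to the base value.
#' @param scenario Efficacy scenario whose parameter is scaled.
#' @param settings Model conventions.
#' @return A tibble of class `chf_sweep` with columns `parameter`, `scale`,
#'   `value` (scaled reduction) and `d_cost`.
#' @export
sweep_efficacy <- function(cohort, costs, tp, horizon_months,
                           which = c("mortality", "hospitalization", "los"),
                           scale_grid = seq(0.5, 1, by = 0.1),
                           scenario = chf_defaults()$scenarios$base,
                           settings = default_settings()) {
  which <- match.arg(which)
  stopifnot(all(scale_grid >= 0 & scale_grid <= 1))
  field <- switch(which,
                  mortality = "mortality_reduction",
                  hospitalization = "hospitalization_reduction",
                  los = "los_reduction")
  out <- purrr::map_dfr(scale_grid, function(s) {
    scen <- scenario
    scen[[field]] <- scenario[[field]] * s
    cmp <- compare_arms(cohort, scen, costs, tp, horizon_months, settings)
    tibble::tibble(parameter = which, scale = s, value = scen[[field]],
                   d_cost = cmp$incremental$cost)
  })
  structure(out, class = c("chf_sweep", class(out)))
}

#' Two-way sensitivity grid over admission cost and monthly fee
#'
#' For each pair (monthly fee, admission cost) the monthly fee replaces the
#' whole TEST bundle and the per-admission cost is overridden; all other cost
#' parameters keep their schedule values. Incremental cost is recorded per
#' cell.
#'
#' @param cohort A `chf_cohort`.
#' @param scenario A `chf_efficacy`.
#' @param tp Usual-care `chf_transitions`.
#' @param horizon_months Horizon in months.
#' @param monthly_fees Monthly telehealth service fees (USD) to evaluate.
#' @param admission_costs Per-admission costs (USD) to evaluate.
#' @param costs Baseline `chf_costs` supplying the remaining parameters.
#' @param settings Model conventions.
#' @return A tibble of class `chf_grid` with columns `monthly_fee`,
#'   `admission_cost`, `d_cost`.
#' @export
sensitivity_grid <- function(cohort, scenario, tp, horizon_months = 36,
                             monthly_fees = seq(50, 450, by = 100),
                             admission_costs = seq(6000, 16000, by = 2000),
                             costs = cost_schedule(),
                             settings = default_settings()) {
  stopifnot(all(monthly_fees >= 0), all(admission_costs >= 0))
  out <- tidyr::expand_grid(monthly_fee = monthly_fees,
                            admission_cost = admission_costs) |>
    purrr::pmap_dfr(function(monthly_fee, admission_cost) {
      cs <- set_monthly_fee(costs, monthly_fee)
      cs$cost_per_admission <- admission_cost
      cmp <- compare_arms(cohort, scenario, cs, tp, horizon_months, settings)
      tibble::tibble(monthly_fee = monthly_fee,
                     admission_cost = admission_cost,
                     d_cost = cmp$incremental$cost)
    })
  structure(out, class = c("chf_grid", class(out)))
}

#' Break-even monthly telehealth fee
#'
#' Solves for the monthly TEST fee at which the incremental cost of telehealth
#' is zero over the given horizon. Total cost is affine in the fee with slope
#' equal to the discounted alive patient-months of the telehealth arm, so the
#' root is closed-form:
#' `fee* = fee0 - d_cost(fee0) / slope`.
#' Returns `NA` ("never") when telehealth is cost-incurring even at a zero
#' fee.
#'
#' @param cohort A `chf_cohort`.
#' @param scenario A `chf_efficacy`.
#' @param costs A `chf_costs` (its current TEST bundle is the reference point).
#' @param tp Usual-care `chf_transitions`.
#' @param horizon_months Horizon in months.
#' @param settings Model conventions.
#' @return Break-even fee in USD per month, or `NA_real_` when no nonnegative
#'   fee achieves cost neutrality.
#' @export
break_even_fee <- function(cohort, scenario, costs, tp, horizon_months,
                           settings = default_settings()) {
  settings <- validate_settings(settings)
  cmp <- compare_arms(cohort, scenario, costs, tp, horizon_months, settings)
  trace_t <- cmp$traces$telehealth
  alive <- cost_exposure(trace_t, half_cycle = settings$half_cycle)
  slope <- sum(alive * discount_factor(seq_along(alive),
                                       costs$annual_discount_rate,
                                       method = settings$discount_method))
  fee0 <- monthly_test_cost(costs)
  fee_star <- fee0 - cmp$incremental$cost / slope
  if (fee_star < 0) NA_real_ else fee_star
}

#' Break-even fee table across cohorts, scenarios and horizons
#'
#' @param config A `chf_config` bundle.
#' @param cohorts,scenarios Labels from the bundle.
#' @param horizons Horizons in months.
#' @return A tibble with one row per cohort x scenario x horizon; `fee` is
#'   `NA` where telehealth can never break even.
#' @export
break_even_table <- function(config = chf_defaults(),
                             cohorts = names(config$cohorts),
                             scenarios = names(config$scenarios),
                             horizons = c(12, 36, 60)) {
  check_labels(cohorts, names(config$cohorts), "cohort")
  check_labels(scenarios, names(config$scenarios), "scenario")
  tidyr::expand_grid(cohort = cohorts, scenario = scenarios,
                     horizon_months = horizons) |>
    purrr::pmap_dfr(function(cohort, scenario, horizon_months) {
      co <- config$cohorts[[cohort]]
      fee <- break_even_fee(co, config$scenarios[[scenario]], config$costs,
                            config$transitions[[co$nyha_label]],
                            horizon_months, config$settings)
      tibble::tibble(cohort = cohort, scenario = scenario,
                     horizon_months = horizon_months, fee = fee)
    })
}

#' Lifetime-cost validation run
#'
#' Usual-care total discounted cost for a newly diagnosed cohort (all mass on
#' `H0`) over a 20-year (240-cycle) horizon — the model's analogue of
#' published lifetime-cost-after-diagnosis estimates.
#'
#' @param tp Usual-care `chf_transitions`.
#' @param costs A `chf_costs`.
#' @param cycles Horizon in months (default 240).
#' @param settings Model conventions.
#' @return A list with `total_cost` (USD per patient), `fraction_dead` at the
#'   end of the horizon, and `life_years`.
#' @export
lifetime_validation <- function(tp = chf_defaults()$transitions[["NYHA II or III"]],
                                costs = cost_schedule(),
                                cycles = 240,
                                settings = default_settings()) {
  cohort <- cohort_spec(c(H0 = 1), horizon_months = cycles, label = "C1")
  trace <- run_horizon(cohort, tp, cycles = cycles)
  ct <- accumulate_costs(trace, "usual", tp, null_efficacy(), costs, settings)
  list(
    total_cost = cost_total(ct),
    fraction_dead = trace$death[nrow(trace)],
    life_years = life_years(trace)
  )
}

#' National yearly cost burden of CHF
#'
#' Usual-care 12-month CHF-attributable cost per patient — hospital admissions
#' plus CHF outpatient care; the non-CHF healthcare channel is excluded
#' because it is not part of the disease's direct burden — for a cohort
#' weighted by admission-status prevalence, scaled to a national patient
#' population.
#'
#' @param tp Usual-care `chf_transitions`.
#' @param costs A `chf_costs`.
#' @param weights Probability weights over the five living states
#'   `H0`..`H4plus` (must sum to 1 within `1e-9`).
#' @param population Number of prevalent patients.
#' @param settings Model conventions.
#' @return A list with `per_patient` (CHF-attributable USD per patient-year)
#'   and `total` (USD per year for the population).
#' @export
national_burden <- function(tp = chf_defaults()$transitions[["NYHA II or III"]],
                            costs = cost_schedule(),
                            weights = c(0.707, 0.103, 0.044, 0.033, 0.113),
                            population = 5e6,
                            settings = default_settings()) {
  if (length(weights) != 5L || any(weights < 0)) {
    stop_invalid("weights", "must be 5 nonnegative values over H0..H4plus")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_invalid("weights", "must sum to 1")
  }
  check_nonneg(population, "population")
  cohort <- cohort_spec(stats::setNames(weights, chf_living_states()),
                        horizon_months = 12, label = "national")
  trace <- run_horizon(cohort, tp, cycles = 12)
  ct <- accumulate_costs(trace, "usual", tp, null_efficacy(), costs, settings)
  per_patient <- sum(ct$admission + ct$outpatient)
  list(per_patient = per_patient, total = per_patient * population)
}

#' Cumulative savings curve over a horizon
#'
#' Month-by-month cumulative incremental cost (and admissions) of telehealth
#' versus usual care, the data behind cost-saving curves as a function of time
#' on the program.
#'
#' @inheritParams compare_arms
#' @return A tibble with columns `cohort`, `month`, `cum_d_cost` (cumulative
#'   telehealth-minus-usual cost) and `cum_d_admissions`.
#' @export
savings_curve <- function(cohort, scenario, costs, tp,
                          horizon_months = cohort$horizon_months,
                          settings = default_settings()) {
  cmp <- compare_arms(cohort, scenario, costs, tp, horizon_months, settings)
  per_u <- cmp$cost_traces$usual$per_cycle_cost
  per_t <- cmp$cost_traces$telehealth$per_cycle_cost
  adm_u <- cmp$traces$usual$expected_admissions[-1]
  adm_t <- cmp$traces$telehealth$expected_admissions[-1]
  tibble::tibble(
    cohort = cohort$label,
    month = seq_len(cmp$horizon_months),
    cum_d_cost = cumsum(per_t - per_u),
    cum_d_admissions = cumsum(adm_t - adm_u)
  )
}
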