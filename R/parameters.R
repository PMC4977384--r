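# Parameter value objects: transition hazards, telehealth efficacy scenarios,
# cost schedule, cohort specifications, and the built-in defaults bundle.

#' Model states
#'
#' The model tracks six states: five living states defined by the number of
#' prior CHF hospital admissions (`H0` through `H4plus`) and an absorbing
#' `death` state.
#'
#' @return Character vector of state names.
#' @export
chf_states <- function() c("H0", "H1", "H2", "H3", "H4plus", "death")

#' @rdname chf_states
#' @export
chf_living_states <- function() chf_states()[1:5]

stop_invalid <- function(field, constraint) {
  rlang::abort(
    sprintf("invalid value for `%s`: %s", field, constraint),
    class = "chfmarkov_validation_error"
  )
}

check_prob <- function(x, field, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_invalid(field, sprintf("must be numeric of length %d with no NA", len))
  }
  if (any(x < 0 | x > 1)) stop_invalid(field, "probabilities must lie in [0, 1]")
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_invalid(field, "must be a single nonnegative number")
  }
  invisible(x)
}

#' Monthly transition hazards
#'
#' Per-cycle (monthly) hazards for the usual-care population: probability of a
#' CHF hospitalization for each living state, probability of death in a cycle
#' without hospitalization, and probability of death conditional on a
#' hospitalization event in the cycle.
#'
#' @param p_hosp_by_state Numeric vector of 5 monthly hospitalization
#'   probabilities, ordered `H0`, `H1`, `H2`, `H3`, `H4plus`.
#' @param p_death_not_hospitalized Monthly probability of death for a patient
#'   who is not hospitalized in the cycle.
#' @param p_death_hospitalized Probability of death conditional on a
#'   hospitalization event in the cycle.
#' @param label Text tag, e.g. `"NYHA II or III"`.
#' @param require_monotone_hosp If `TRUE`, require `p_hosp_by_state` to be
#'   nondecreasing in the admission count (holds for the built-in hazard
#'   tables; user configurations may relax it).
#' @return An object of class `chf_transitions`.
#' @export
transition_parameters <- function(p_hosp_by_state,
                                  p_death_not_hospitalized,
                                  p_death_hospitalized,
                                  label = "custom",
                                  require_monotone_hosp = FALSE) {
  check_prob(p_hosp_by_state, "p_hosp_by_state", len = 5L)
  check_prob(p_death_not_hospitalized, "p_death_not_hospitalized")
  check_prob(p_death_hospitalized, "p_death_hospitalized")
  if (require_monotone_hosp && is.unsorted(p_hosp_by_state)) {
    stop_invalid("p_hosp_by_state", "must be nondecreasing in admission count")
  }
  structure(
    list(
      p_hosp_by_state = stats::setNames(as.numeric(p_hosp_by_state), chf_living_states()),
      p_death_not_hospitalized = as.numeric(p_death_not_hospitalized),
      p_death_hospitalized = as.numeric(p_death_hospitalized),
      label = as.character(label)
    ),
    class = "chf_transitions"
  )
}

#' @export
print.chf_transitions <- function(x, ...) {
  cat("<chf_transitions> ", x$label, "\n", sep = "")
  cat("  p(hospitalization) by state:\n")
  print(x$p_hosp_by_state)
  cat("  p(death | not hospitalized): ", x$p_death_not_hospitalized, "\n", sep = "")
  cat("  p(death | hospitalized):     ", x$p_death_hospitalized, "\n", sep = "")
  invisible(x)
}

#' Telehealth efficacy scenario
#'
#' Bundle of the five clinical performance parameters of a telehealth program:
#' detection sensitivity and specificity of the home monitoring TEST, and the
#' proportional reductions in mortality, CHF hospitalization, and hospital
#' length of stay attributed to early intervention.
#'
#' @param sensitivity,specificity Detection performance of home-based
#'   exacerbation monitoring, fractions in `[0, 1]`.
#' @param mortality_reduction,hospitalization_reduction Proportional reductions
#'   applied to the usual-care death and hospitalization hazards.
#' @param los_reduction Proportional shortening of hospital length of stay,
#'   modelled as a per-admission cost reduction for detected admissions.
#' @param label Text tag (`"best"`, `"base"`, `"worst"`, or custom).
#' @return An object of class `chf_efficacy`.
#' @export
efficacy_scenario <- function(sensitivity,
                              specificity,
                              mortality_reduction,
                              hospitalization_reduction,
                              los_reduction,
                              label = "custom") {
  for (f in c("sensitivity", "specificity", "mortality_reduction",
              "hospitalization_reduction", "los_reduction")) {
    check_prob(get(f), f)
  }
  structure(
    list(
      sensitivity = as.numeric(sensitivity),
      specificity = as.numeric(specificity),
      mortality_reduction = as.numeric(mortality_reduction),
      hospitalization_reduction = as.numeric(hospitalization_reduction),
      los_reduction = as.numeric(los_reduction),
      label = as.character(label)
    ),
    class = "chf_efficacy"
  )
}

#' @export
print.chf_efficacy <- function(x, ...) {
  cat("<chf_efficacy> ", x$label, "\n", sep = "")
  cat(sprintf("  SEN %.2f  SPE %.2f  mortality -%d%%  hospitalization -%d%%  LOS -%d%%\n",
              x$sensitivity, x$specificity,
              round(100 * x$mortality_reduction),
              round(100 * x$hospitalization_reduction),
              round(100 * x$los_reduction)))
  invisible(x)
}

#' A zero-effect efficacy scenario
#'
#' Convenience constructor for the null intervention: all reductions zero, so
#' the telehealth arm's clinical trajectory is identical to usual care.
#' Sensitivity and specificity default to 0 and 1 so no TREAT episodes are
#' triggered either.
#'
#' @param sensitivity,specificity Detection parameters; defaults trigger no
#'   treatment episodes.
#' @return A `chf_efficacy` object.
#' @export
null_efficacy <- function(sensitivity = 0, specificity = 1) {
  efficacy_scenario(sensitivity, specificity, 0, 0, 0, label = "null")
}

#' Cost schedule
#'
#' All dollar parameters of the model (2013 USD, nominal) and the annual
#' discount rate. Annual costs accrue uniformly, one twelfth per monthly cycle.
#'
#' @param cost_per_admission USD per CHF hospitalization event.
#' @param annual_chf_outpatient USD per alive patient-year of CHF outpatient care.
#' @param annual_non_chf USD per alive patient-year of non-CHF healthcare.
#' @param monthly_install Amortized install/uninstall cost, USD per telehealth
#'   patient-month.
#' @param monthly_monitoring Monitoring cost, USD per telehealth patient-month.
#' @param monthly_case_manager Case manager cost, USD per telehealth patient-month.
#' @param treat_physician Physician contact / medication initiation cost, USD
#'   per detected episode.
#' @param treat_nurse_visit Nurse home visit cost, USD per detected episode.
#' @param annual_discount_rate Annual discount rate (fraction).
#' @return An object of class `chf_costs`.
#' @export
cost_schedule <- function(cost_per_admission = 12000,
                          annual_chf_outpatient = 1700,
                          annual_non_chf = 10000,
                          monthly_install = 15,
                          monthly_monitoring = 80,
                          monthly_case_manager = 125,
                          treat_physician = 52,
                          treat_nurse_visit = 135,
                          annual_discount_rate = 0.03) {
  args <- as.list(environment())
  purrr::iwalk(args, check_nonneg)
  structure(purrr::map(args, as.numeric), class = "chf_costs")
}

#' Derived monthly TEST cost (monitoring bundle)
#'
#' Sum of the amortized install, monitoring, and case-manager components;
#' `$220`/month for the default schedule.
#'
#' @param costs A `chf_costs` object.
#' @return USD per telehealth patient-month.
#' @export
monthly_test_cost <- function(costs) {
  costs$monthly_install + costs$monthly_monitoring + costs$monthly_case_manager
}

#' Derived TREAT cost per detected episode
#'
#' Physician contact plus nurse home visit; `$187` per episode for the default
#' schedule.
#'
#' @param costs A `chf_costs` object.
#' @return USD per detected episode.
#' @export
treat_cost_per_episode <- function(costs) {
  costs$treat_physician + costs$treat_nurse_visit
}

#' Replace the monthly TEST bundle by a flat fee
#'
#' Used by the two-way sensitivity and break-even analyses, where the monthly
#' telehealth service fee replaces the whole install + monitoring +
#' case-manager bundle; TREAT costs are untouched.
#'
#' @param costs A `chf_costs` object.
#' @param fee USD per telehealth patient-month.
#' @return A `chf_costs` object with `monthly_test_cost()` equal to `fee`.
#' @export
set_monthly_fee <- function(costs, fee) {
  check_nonneg(fee, "fee")
  costs$monthly_install <- as.numeric(fee)
  costs$monthly_monitoring <- 0
  costs$monthly_case_manager <- 0
  costs
}

#' @export
print.chf_costs <- function(x, ...) {
  cat("<chf_costs>\n")
  cat(sprintf("  admission $%s   outpatient $%s/yr   non-CHF $%s/yr\n",
              format(x$cost_per_admission, big.mark = ","),
              format(x$annual_chf_outpatient, big.mark = ","),
              format(x$annual_non_chf, big.mark = ",")))
  cat(sprintf("  TEST $%d/mo (install %d + monitoring %d + case manager %d)\n",
              round(monthly_test_cost(x)), round(x$monthly_install),
              round(x$monthly_monitoring), round(x$monthly_case_manager)))
  cat(sprintf("  TREAT $%d/episode   discount %.1f%%/yr\n",
              round(treat_cost_per_episode(x)), 100 * x$annual_discount_rate))
  invisible(x)
}

#' Cohort specification
#'
#' Initial probability mass over the six model states, a default horizon, and
#' which NYHA hazard column applies.
#'
#' @param initial_distribution Numeric probability mass over the states. Either
#'   a named vector using names from [chf_states()] (missing states get 0) or
#'   an unnamed vector of length 5 (living states) or 6. Must sum to 1 within
#'   `1e-12`.
#' @param horizon_months Default number of monthly cycles for this cohort.
#' @param nyha_label Which transition-hazard column applies.
#' @param label Text tag (`"C1"`, `"C2"`, `"C3"`, or custom).
#' @return An object of class `chf_cohort`.
#' @export
cohort_spec <- function(initial_distribution,
                        horizon_months = 60,
                        nyha_label = "NYHA II or III",
                        label = "custom") {
  states <- chf_states()
  x <- initial_distribution
  if (is.null(names(x))) {
    if (length(x) == 5L) x <- c(x, 0)
    if (length(x) != 6L) {
      stop_invalid("initial_distribution", "unnamed vector must have length 5 or 6")
    }
    names(x) <- states
  } else {
    if (!all(names(x) %in% states)) {
      stop_invalid("initial_distribution",
                   paste("names must be among:", paste(states, collapse = ", ")))
    }
    full <- stats::setNames(numeric(6), states)
    full[names(x)] <- x
    x <- full
  }
  if (any(x < 0 | x > 1)) stop_invalid("initial_distribution", "mass must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-12) {
    stop_invalid("initial_distribution", "mass must sum to 1 within 1e-12")
  }
  if (!is.numeric(horizon_months) || length(horizon_months) != 1L ||
      is.na(horizon_months) || horizon_months < 1 ||
      horizon_months != round(horizon_months)) {
    stop_invalid("horizon_months", "must be a positive integer")
  }
  structure(
    list(
      initial_distribution = x,
      horizon_months = as.integer(horizon_months),
      nyha_label = as.character(nyha_label),
      label = as.character(label)
    ),
    class = "chf_cohort"
  )
}

#' @export
print.chf_cohort <- function(x, ...) {
  cat("<chf_cohort> ", x$label, " (", x$nyha_label, ", horizon ",
      x$horizon_months, " months)\n", sep = "")
  print(x$initial_distribution)
  invisible(x)
}

default_settings <- function() {
  list(
    half_cycle = FALSE,        # credit full months to patients alive at cycle start
    efficacy_gating = "sen",   # hazard reductions reach only detected exacerbations
    los_gating = "all",        # LOS saving applies to every telehealth admission
    treat_trigger = "usual",   # TREAT frequency driven by usual-care hazards
    discount_method = "annual",
    discount_life_years = TRUE,
    ly_convention = "end"      # person-time credited to cycle survivors
  )
}

validate_settings <- function(settings) {
  base <- default_settings()
  unknown <- setdiff(names(settings), names(base))
  if (length(unknown) > 0) {
    stop_invalid(paste0("settings.", unknown[1]), "unknown setting")
  }
  out <- utils::modifyList(base, settings)
  if (!out$efficacy_gating %in% c("sen", "none")) {
    stop_invalid("settings.efficacy_gating", "must be 'sen' or 'none'")
  }
  if (!out$los_gating %in% c("sen", "all")) {
    stop_invalid("settings.los_gating", "must be 'sen' or 'all'")
  }
  if (!out$treat_trigger %in% c("usual", "adjusted")) {
    stop_invalid("settings.treat_trigger", "must be 'usual' or 'adjusted'")
  }
  if (!out$discount_method %in% c("monthly", "annual")) {
    stop_invalid("settings.discount_method", "must be 'monthly' or 'annual'")
  }
  if (!out$ly_convention %in% c("end", "start", "half")) {
    stop_invalid("settings.ly_convention", "must be 'end', 'start' or 'half'")
  }
  for (f in c("half_cycle", "discount_life_years")) {
    if (!is.logical(out[[f]]) || length(out[[f]]) != 1L || is.na(out[[f]])) {
      stop_invalid(paste0("settings.", f), "must be TRUE or FALSE")
    }
  }
  out
}

#' Built-in default parameter bundle
#'
#' The complete base configuration of the model: both NYHA hazard columns, the
#' three efficacy scenarios (best / base / worst), the cost schedule with 3%
#' annual discounting, and the three reference cohorts:
#' \describe{
#'   \item{C1}{low risk — all mass on `H0` (no prior admissions);}
#'   \item{C2}{intermediate risk — 30%/30%/40% on `H1`/`H2`/`H3`;}
#'   \item{C3}{high risk — all mass on `H4plus`.}
#' }
#' All cohorts use the NYHA II or III hazard column.
#'
#' @return A list of class `chf_config` with elements `transitions`,
#'   `scenarios`, `costs`, `cohorts`, and `settings`.
#' @export
chf_defaults <- function() {
  transitions <- list(
    "NYHA II or III" = transition_parameters(
      p_hosp_by_state = c(0.008, 0.052, 0.106, 0.121, 0.180),
      p_death_not_hospitalized = 0.007,
      p_death_hospitalized = 0.100,
      label = "NYHA II or III",
      require_monotone_hosp = TRUE
    ),
    "NYHA III or IV" = transition_parameters(
      p_hosp_by_state = c(0.008, 0.168, 0.213, 0.268, 0.334),
      p_death_not_hospitalized = 0.010,
      p_death_hospitalized = 0.100,
      label = "NYHA III or IV",
      require_monotone_hosp = TRUE
    )
  )
  scenarios <- list(
    best = efficacy_scenario(0.90, 0.90, 0.29, 0.38, 0.30, label = "best"),
    base = efficacy_scenario(0.80, 0.80, 0.24, 0.28, 0.25, label = "base"),
    worst = efficacy_scenario(0.70, 0.70, 0.19, 0.18, 0.20, label = "worst")
  )
  cohorts <- list(
    C1 = cohort_spec(c(H0 = 1), label = "C1"),
    C2 = cohort_spec(c(H1 = 0.30, H2 = 0.30, H3 = 0.40), label = "C2"),
    C3 = cohort_spec(c(H4plus = 1), label = "C3")
  )
  structure(
    list(
      transitions = transitions,
      scenarios = scenarios,
      costs = cost_schedule(),
      cohorts = cohorts,
      settings = default_settings()
    ),
    class = "chf_config"
  )
}

#' @export
print.chf_config <- function(x, ...) {
  cat("<chf_config>\n")
  cat("  transitions: ", paste(names(x$transitions), collapse = ", "), "\n", sep = "")
  cat("  scenarios:   ", paste(names(x$scenarios), collapse = ", "), "\n", sep = "")
  cat("  cohorts:     ", paste(names(x$cohorts), collapse = ", "), "\n", sep = "")
  cat("  settings:    ",
      paste(names(x$settings), unlist(lapply(x$settings, as.character)),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
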