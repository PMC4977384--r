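# Economic layer: per-cycle discounted cost accrual for each arm.
#
# Cost channels per cycle:
#   admission  — expected hospitalization events x per-admission cost; in the
#                telehealth arm detected admissions are billed at a LOS-reduced
#                rate (see `los_gating`).
#   outpatient — CHF outpatient care, 1/12 of the annual figure per alive month.
#   non_chf    — other healthcare, 1/12 of the annual figure per alive month.
#   test       — telehealth monitoring bundle per alive patient-month.
#   treat      — early-intervention episodes triggered by positive monitoring
#                tests (true positives among exacerbations, false positives
#                among the rest).

#' Discount factor for a monthly cycle
#'
#' End-of-cycle convention: cash flows in cycle `t` (1-based months) are
#' discounted by `(1 + rate)^(-t/12)`. The `"annual"` method instead groups
#' cycles into model years and discounts year `k` by `(1 + rate)^-(k-1)`.
#'
#' @param cycle 1-based month index (vectorized).
#' @param annual_rate Annual discount rate.
#' @param method `"monthly"` (default) or `"annual"` granularity.
#' @return Multiplier(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle, annual_rate, method = c("monthly", "annual")) {
  method <- match.arg(method)
  stopifnot(all(cycle >= 1), annual_rate >= 0)
  if (method == "monthly") {
    (1 + annual_rate)^(-cycle / 12)
  } else {
    (1 + annual_rate)^(-(ceiling(cycle / 12) - 1))
  }
}

#' Expected TREAT cost per alive patient-cycle
#'
#' A positive monitoring test triggers one early-treatment episode (physician
#' contact + nurse visit). Positives arise from true exacerbations detected
#' with probability SEN and from false alarms in the remaining patients with
#' probability `1 - SPE`:
#' `[SEN * p_ex + (1 - SPE) * (1 - p_ex)] * TREAT`.
#'
#' @param p_exacerbation Probability that an alive patient has an exacerbation
#'   (hospitalization-triggering event) this cycle; vectorized.
#' @param eff A `chf_efficacy` object.
#' @param costs A `chf_costs` object.
#' @return USD per alive patient-cycle.
#' @export
expected_treat_cost <- function(p_exacerbation, eff, costs) {
  p_pos <- eff$sensitivity * p_exacerbation +
    (1 - eff$specificity) * (1 - p_exacerbation)
  p_pos * treat_cost_per_episode(costs)
}

# Occupancy-weighted exacerbation probability among alive patients.
exacerbation_probability <- function(occupancy, tp) {
  living <- occupancy[1:5]
  alive <- sum(living)
  if (alive <= 0) return(0)
  sum(living * tp$p_hosp_by_state) / alive
}

# Per-admission cost multiplier in the telehealth arm: detected admissions
# are billed at 1 - los_reduction. Under "all" gating every admission gets
# the reduction; under "sen" gating only the detected fraction does. When
# hazard reductions are themselves detection-gated, detected exacerbations
# are admitted at a reduced rate, so the detected share of admissions is
# SEN*(1-hr) / (1 - SEN*hr) rather than SEN.
los_multiplier <- function(eff, los_gating, efficacy_gating = "none") {
  if (los_gating == "all") return(1 - eff$los_reduction)
  if (los_gating != "sen") {
    rlang::abort("`los_gating` must be 'sen' or 'all'",
                 class = "chfmarkov_argument_error")
  }
  sen <- eff$sensitivity
  detected_share <- if (efficacy_gating == "sen") {
    hr <- eff$hospitalization_reduction
    if (sen * hr >= 1) 1 else sen * (1 - hr) / (1 - sen * hr)
  } else {
    sen
  }
  detected_share * (1 - eff$los_reduction) + (1 - detected_share)
}

#' Discounted cost components for one cycle
#'
#' @param arm `"usual"` or `"telehealth"`.
#' @param occupancy Named state-occupancy vector at cycle start.
#' @param expected_admissions Expected hospitalization events during the cycle
#'   (from the arm's own trace).
#' @param tp_usual Usual-care `chf_transitions` (drives the TREAT trigger).
#' @param eff A `chf_efficacy` object; ignored for the usual arm.
#' @param costs A `chf_costs` object.
#' @param cycle 1-based month index, used for discounting.
#' @param alive Alive exposure for the cycle; defaults to the alive mass in
#'   `occupancy` (start-of-cycle convention).
#' @param settings Model conventions, see [chf_defaults()]`$settings`.
#' @return Named numeric vector of discounted components
#'   `admission`, `outpatient`, `non_chf`, `test`, `treat`.
#' @export
cycle_cost <- function(arm, occupancy, expected_admissions, tp_usual, eff,
                       costs, cycle, alive = NULL,
                       settings = default_settings()) {
  if (!arm %in% c("usual", "telehealth")) {
    rlang::abort(sprintf("unknown arm '%s': must be 'usual' or 'telehealth'", arm),
                 class = "chfmarkov_argument_error")
  }
  settings <- validate_settings(settings)
  if (is.null(alive)) alive <- sum(occupancy[1:5])
  out <- c(admission = 0, outpatient = 0, non_chf = 0, test = 0, treat = 0)
  out["outpatient"] <- alive * costs$annual_chf_outpatient / 12
  out["non_chf"] <- alive * costs$annual_non_chf / 12
  if (arm == "usual") {
    out["admission"] <- expected_admissions * costs$cost_per_admission
  } else {
    out["admission"] <- expected_admissions * costs$cost_per_admission *
      los_multiplier(eff, settings$los_gating, settings$efficacy_gating)
    out["test"] <- alive * monthly_test_cost(costs)
    tp_trigger <- if (settings$treat_trigger == "usual") {
      tp_usual
    } else {
      adjust_hazards(tp_usual, effective_efficacy(eff, settings$efficacy_gating))
    }
    p_ex <- exacerbation_probability(occupancy, tp_trigger)
    out["treat"] <- alive * expected_treat_cost(p_ex, eff, costs)
  }
  out * discount_factor(cycle, costs$annual_discount_rate,
                        method = settings$discount_method)
}

#' Accumulate discounted costs over a cohort trace
#'
#' Applies [cycle_cost()] to every cycle of a trace and returns the per-cycle
#' component breakdown plus the discounted total.
#'
#' @param trace A `chf_trace` from [run_horizon()]; for the telehealth arm it
#'   must have been produced with efficacy-adjusted hazards.
#' @param arm `"usual"` or `"telehealth"`.
#' @param tp_usual Usual-care `chf_transitions`.
#' @param eff A `chf_efficacy` object (ignored for the usual arm; pass
#'   [null_efficacy()] if none applies).
#' @param costs A `chf_costs` object.
#' @param settings Model conventions, see [chf_defaults()]`$settings`.
#' @return A tibble of class `chf_cost_trace` with columns `cycle`,
#'   `admission`, `outpatient`, `non_chf`, `test`, `treat`, `per_cycle_cost`;
#'   the discounted total is in `attr(x, "total")` and via [cost_total()].
#' @export
accumulate_costs <- function(trace, arm, tp_usual, eff, costs,
                             settings = default_settings()) {
  stopifnot(inherits(trace, "chf_trace"))
  settings <- validate_settings(settings)
  cycles <- attr(trace, "cycles")
  states <- chf_states()
  occ <- as.matrix(trace[, states])
  alive <- cost_exposure(trace, half_cycle = settings$half_cycle)
  comp <- purrr::map(seq_len(cycles), function(t) {
    cycle_cost(
      arm = arm,
      occupancy = occ[t, ],                  # start-of-cycle occupancy
      expected_admissions = trace$expected_admissions[t + 1L],
      tp_usual = tp_usual, eff = eff, costs = costs,
      cycle = t, alive = alive[t], settings = settings
    )
  })
  out <- tibble::as_tibble(do.call(rbind, comp))
  out <- dplyr::mutate(out,
                       cycle = seq_len(cycles), .before = 1)
  out <- dplyr::mutate(out,
                       per_cycle_cost = .data$admission + .data$outpatient +
                         .data$non_chf + .data$test + .data$treat)
  structure(out,
            class = c("chf_cost_trace", class(out)),
            arm = arm,
            total = sum(out$per_cycle_cost))
}

#' Total discounted cost of a cost trace
#'
#' @param cost_trace A `chf_cost_trace` from [accumulate_costs()].
#' @return USD per initial patient, discounted.
#' @export
cost_total <- function(cost_trace) {
  stopifnot(inherits(cost_trace, "chf_cost_trace"))
  attr(cost_trace, "total")
}

#' @export
print.chf_cost_trace <- function(x, ...) {
  cat(sprintf("<chf_cost_trace> %s arm, total $%.2f (discounted)\n",
              attr(x, "arm"), attr(x, "total")))
  NextMethod()
}
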