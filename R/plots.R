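# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot state occupancy over time
#'
#' Stacked-area chart of cohort probability mass per state across cycles.
#'
#' @param object A `chf_trace` from [run_horizon()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chf_trace <- function(object, ...) {
  states <- chf_states()
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("cycle", states)],
                              cols = dplyr::all_of(states),
                              names_to = "state", values_to = "mass") |>
    dplyr::mutate(state = factor(.data$state, levels = rev(states)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$mass,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Month", y = "Cohort fraction", fill = "State",
                  title = sprintf("State occupancy — cohort %s",
                                  attr(object, "cohort_label"))) +
    ggplot2::theme_minimal()
}

#' Plot a one-way efficacy sweep
#'
#' Incremental cost as the selected reduction parameter is scaled from partial
#' to full effectiveness.
#'
#' @param object A `chf_sweep` from [sweep_efficacy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chf_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = -.data$d_cost,
                                       colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Efficacy scale (1 = full effectiveness)",
                  y = "Cost saving per patient (USD)",
                  colour = "Parameter") +
    ggplot2::theme_minimal()
}

#' Plot a two-way sensitivity grid
#'
#' Tile map of incremental cost over monthly fee x admission cost.
#'
#' @param object A `chf_grid` from [sensitivity_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chf_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$admission_cost),
                                       y = factor(.data$monthly_fee),
                                       fill = .data$d_cost)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$d_cost)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2c7bb6", mid = "white",
                                  high = "#d7191c", midpoint = 0) +
    ggplot2::labs(x = "Admission cost (USD)", y = "Monthly fee (USD)",
                  fill = "Δ cost") +
    ggplot2::theme_minimal()
}

#' Plot cumulative savings curves
#'
#' Cumulative cost saving (usual minus telehealth, so positive = saving) as a
#' function of months on the program, one line per cohort.
#'
#' @param curves A tibble from [savings_curve()], possibly row-bound across
#'   cohorts.
#' @return A ggplot object.
#' @export
plot_savings_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$month, y = -.data$cum_d_cost,
                                       colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Months on telehealth program",
                  y = "Cumulative cost saving per patient (USD)",
                  colour = "Cohort") +
    ggplot2::theme_minimal()
}
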