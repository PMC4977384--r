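# YAML configuration I/O. Any section absent from the file falls back to the
# built-in defaults; every fallback is reported via message().

#' Read a model configuration file
#'
#' Reads a YAML configuration (see `inst/extdata/config-example.yaml` for the
#' canonical schema) and returns a fully validated `chf_config` bundle.
#' Sections or fields missing from the file fall back to the built-in defaults
#' of [chf_defaults()]; each fallback is reported via `message()`.
#'
#' Recognised top-level sections: `transitions` (list of hazard columns),
#' `scenarios` (list of efficacy scenarios), `costs` (cost schedule fields),
#' `cohorts` (list of cohort specs), `settings` (model conventions).
#'
#' @param path Path to a YAML file.
#' @return A `chf_config` bundle.
#' @export
read_chf_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("configuration file not found: %s", path),
                 class = "chfmarkov_io_error")
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      rlang::abort(sprintf("failed to parse configuration file %s: %s",
                           path, conditionMessage(e)),
                   class = "chfmarkov_parse_error")
    }
  )
  if (is.null(raw)) raw <- list()
  known <- c("transitions", "scenarios", "costs", "cohorts", "settings")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown configuration section: %s", unknown[1]),
                 class = "chfmarkov_parse_error")
  }
  defaults <- chf_defaults()
  out <- defaults

  if (is.null(raw$transitions)) {
    message("config: no `transitions` section; using built-in hazard tables")
  } else {
    out$transitions <- purrr::map(raw$transitions, parse_transitions)
    names(out$transitions) <- purrr::map_chr(out$transitions, "label")
  }
  if (is.null(raw$scenarios)) {
    message("config: no `scenarios` section; using built-in efficacy scenarios")
  } else {
    out$scenarios <- purrr::map(raw$scenarios, parse_scenario)
    names(out$scenarios) <- purrr::map_chr(out$scenarios, "label")
  }
  if (is.null(raw$costs)) {
    message("config: no `costs` section; using built-in cost schedule")
  } else {
    out$costs <- parse_costs(raw$costs)
  }
  if (is.null(raw$cohorts)) {
    message("config: no `cohorts` section; using built-in cohorts C1/C2/C3")
  } else {
    out$cohorts <- purrr::map(raw$cohorts, parse_cohort)
    names(out$cohorts) <- purrr::map_chr(out$cohorts, "label")
  }
  if (is.null(raw$settings)) {
    message("config: no `settings` section; using default model conventions")
  } else {
    out$settings <- validate_settings(raw$settings)
  }
  for (co in out$cohorts) {
    if (!co$nyha_label %in% names(out$transitions)) {
      stop_invalid("cohorts.nyha_label",
                   sprintf("cohort '%s' references unknown hazard column '%s'",
                           co$label, co$nyha_label))
    }
  }
  out
}

require_fields <- function(x, fields, section) {
  missing <- setdiff(fields, names(x))
  if (length(missing) > 0) {
    rlang::abort(sprintf("configuration section `%s` is missing key `%s`",
                         section, missing[1]),
                 class = "chfmarkov_parse_error")
  }
}

parse_transitions <- function(x) {
  require_fields(x, c("label", "p_hosp_by_state", "p_death_not_hospitalized",
                      "p_death_hospitalized"), "transitions")
  transition_parameters(
    p_hosp_by_state = unlist(x$p_hosp_by_state, use.names = FALSE),
    p_death_not_hospitalized = x$p_death_not_hospitalized,
    p_death_hospitalized = x$p_death_hospitalized,
    label = x$label
  )
}

parse_scenario <- function(x) {
  require_fields(x, c("label", "sensitivity", "specificity",
                      "mortality_reduction", "hospitalization_reduction",
                      "los_reduction"), "scenarios")
  efficacy_scenario(
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    mortality_reduction = x$mortality_reduction,
    hospitalization_reduction = x$hospitalization_reduction,
    los_reduction = x$los_reduction,
    label = x$label
  )
}

parse_costs <- function(x) {
  fields <- names(formals(cost_schedule))
  unknown <- setdiff(names(x), fields)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("configuration section `costs` has unknown key `%s`",
                         unknown[1]),
                 class = "chfmarkov_parse_error")
  }
  do.call(cost_schedule, x)
}

parse_cohort <- function(x) {
  require_fields(x, c("label", "initial_distribution"), "cohorts")
  dist <- x$initial_distribution
  if (is.list(dist)) dist <- unlist(dist)
  cohort_spec(
    initial_distribution = dist,
    horizon_months = x$horizon_months %||% 60,
    nyha_label = x$nyha_label %||% "NYHA II or III",
    label = x$label
  )
}

#' Write a model configuration file
#'
#' Serializes a `chf_config` bundle to YAML such that
#' `read_chf_config(write_chf_config(cfg, path))` reproduces the bundle
#' field-for-field.
#'
#' @param config A `chf_config` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chf_config <- function(config, path) {
  stopifnot(inherits(config, "chf_config"))
  raw <- list(
    transitions = purrr::map(unname(config$transitions), function(tp) {
      list(
        label = tp$label,
        p_hosp_by_state = unname(tp$p_hosp_by_state),
        p_death_not_hospitalized = tp$p_death_not_hospitalized,
        p_death_hospitalized = tp$p_death_hospitalized
      )
    }),
    scenarios = purrr::map(unname(config$scenarios), function(sc) {
      sc[c("label", "sensitivity", "specificity", "mortality_reduction",
           "hospitalization_reduction", "los_reduction")]
    }),
    costs = unclass(config$costs),
    cohorts = purrr::map(unname(config$cohorts), function(co) {
      list(
        label = co$label,
        initial_distribution = as.list(co$initial_distribution),
        horizon_months = co$horizon_months,
        nyha_label = co$nyha_label
      )
    }),
    settings = config$settings
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}
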