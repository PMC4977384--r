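# Shared fixtures built in code.

default_config <- chf_defaults()
tp_nyha23 <- default_config$transitions[["NYHA II or III"]]
tp_nyha34 <- default_config$transitions[["NYHA III or IV"]]
base_scenario <- default_config$scenarios$base
default_costs <- default_config$costs
shipped_settings <- default_config$settings

# hazards that freeze the cohort in place
tp_zero <- transition_parameters(rep(0, 5), 0, 0, label = "null")

# a cohort spread over several states, for conservation-style properties
mixed_cohort <- cohort_spec(
  c(H0 = 0.2, H1 = 0.2, H2 = 0.2, H3 = 0.2, H4plus = 0.1, death = 0.1),
  horizon_months = 24, label = "mixed"
)

zero_costs <- cost_schedule(0, 0, 0, 0, 0, 0, 0, 0, annual_discount_rate = 0)

random_transitions <- function() {
  transition_parameters(
    p_hosp_by_state = sort(stats::runif(5, 0, 0.4)),
    p_death_not_hospitalized = stats::runif(1, 0, 0.05),
    p_death_hospitalized = stats::runif(1, 0, 0.3),
    label = "random"
  )
}

random_scenario <- function() {
  efficacy_scenario(
    sensitivity = stats::runif(1),
    specificity = stats::runif(1),
    mortality_reduction = stats::runif(1),
    hospitalization_reduction = stats::runif(1),
    los_reduction = stats::runif(1),
    label = "random"
  )
}

random_cohort <- function(horizon = 12) {
  mass <- stats::runif(6)
  cohort_spec(setNames(mass / sum(mass), chf_states()),
              horizon_months = horizon, label = "random")
}
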