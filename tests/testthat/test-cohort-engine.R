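# State-transition engine: hazard adjustment, single cycles, horizons,
# and conservation/monotonicity properties.

test_that("efficacy multiplies hazards proportionally and zero efficacy is identity", {
  adj <- adjust_hazards(tp_nyha23, base_scenario)
  expect_equal(unname(adj$p_hosp_by_state["H2"]), 0.106 * 0.72) # = 0.07632
  expect_equal(adj$p_death_not_hospitalized, 0.007 * 0.76)      # = 0.00532
  expect_equal(adj$p_death_hospitalized, 0.100 * 0.76)
  null_adj <- adjust_hazards(tp_nyha23, null_efficacy())
  expect_equal(null_adj$p_hosp_by_state, tp_nyha23$p_hosp_by_state)
  expect_equal(null_adj$p_death_not_hospitalized,
               tp_nyha23$p_death_not_hospitalized)
})

test_that("detection gating scales the reductions by sensitivity only", {
  gated <- effective_efficacy(base_scenario, "sen")
  expect_equal(gated$mortality_reduction, 0.24 * 0.80)
  expect_equal(gated$hospitalization_reduction, 0.28 * 0.80)
  expect_equal(gated$los_reduction, 0.25)        # LOS acts on costs, ungated here
  expect_equal(gated$sensitivity, 0.80)
  expect_equal(effective_efficacy(base_scenario, "none"), base_scenario)
})

test_that("one cycle resolves hospitalization first, then conditional death", {
  # all mass on H0: event-tree enumeration gives the expected rates
  state <- setNames(c(1, 0, 0, 0, 0, 0), chf_states())
  out <- step_cycle(state, tp_nyha23)
  expect_equal(out$expected_admissions, 0.008)
  expect_equal(out$expected_deaths, 0.008 * 0.100 + 0.992 * 0.007) # 0.007744
  expect_equal(sum(out$state), 1)
  expect_equal(unname(out$state["H1"]), 0.008 * 0.9)   # survivors advance one state
  # absorbing death state
  dead <- setNames(c(0, 0, 0, 0, 0, 1), chf_states())
  out_dead <- step_cycle(dead, tp_nyha23)
  expect_equal(out_dead$state, dead)
  expect_equal(out_dead$expected_admissions, 0)
  expect_equal(out_dead$expected_deaths, 0)
  # null dynamics
  out_null <- step_cycle(state, tp_zero)
  expect_equal(out_null$state, state)
  expect_equal(out_null$expected_admissions, 0)
})

test_that("H4plus is a ceiling: survivors of admission stay in H4plus", {
  state <- setNames(c(0, 0, 0, 0, 1, 0), chf_states())
  out <- step_cycle(state, tp_nyha23)
  expect_equal(unname(out$state["H4plus"]),
               0.180 * 0.9 + 0.820 * 0.993)
  expect_equal(out$expected_admissions, 0.180)
})

test_that("run_horizon records a consistent trace and validates its arguments", {
  co <- default_config$cohorts$C1
  expect_error(run_horizon(co, tp_nyha23, cycles = 0), "positive integer")
  # static cohort under zero hazards
  trc0 <- run_horizon(co, tp_zero, cycles = 12)
  expect_equal(as.numeric(trc0[13, chf_states()]),
               unname(co$initial_distribution))
  expect_equal(total_admissions(trc0), 0)
  # deaths conservation on a mixed cohort
  trc <- run_horizon(mixed_cohort, tp_nyha23, cycles = 24)
  expect_equal(sum(trc$expected_deaths),
               trc$death[nrow(trc)] - trc$death[1], tolerance = 1e-10)
  # one-cycle admission rate is a hazard lookup for a point-mass cohort
  trc3 <- run_horizon(default_config$cohorts$C3, tp_nyha23, cycles = 1)
  expect_equal(trc3$expected_admissions[2], 0.180)
})

test_that("probability mass is conserved and death mass is monotone", {
  set.seed(101)
  for (i in 1:25) {
    trc <- run_horizon(random_cohort(), random_transitions(), cycles = 12)
    sums <- rowSums(trc[, chf_states()])
    expect_true(all(abs(sums - 1) < 1e-10))
    expect_true(all(diff(trc$death) >= -1e-12))
    expect_true(all(trc$expected_admissions >= 0))
  }
})

test_that("life years count survival time in years under each convention", {
  co <- default_config$cohorts$C1
  trc0 <- run_horizon(co, tp_zero, cycles = 60)
  expect_equal(life_years(trc0), 5.0)                    # immortal cohort
  expect_equal(life_years(trc0, convention = "end"), 5.0)
  dead <- cohort_spec(c(death = 1), label = "dead")
  expect_equal(life_years(run_horizon(dead, tp_nyha23, cycles = 12)), 0)
  # end-of-cycle credit is strictly below start-of-cycle when deaths occur
  trc <- run_horizon(mixed_cohort, tp_nyha23, cycles = 24)
  expect_lt(life_years(trc, convention = "end"), life_years(trc, "start"))
  expect_equal(life_years(trc, convention = "half"),
               (life_years(trc, "start") + life_years(trc, "end")) / 2)
})

test_that("telehealth survival dominates usual care cycle by cycle", {
  set.seed(202)
  for (i in 1:10) {
    scen <- random_scenario()
    co <- random_cohort()
    trc_u <- run_horizon(co, tp_nyha23, cycles = 24)
    trc_t <- run_horizon(co, adjust_hazards(tp_nyha23, scen), cycles = 24)
    expect_true(all(trc_t$death <= trc_u$death + 1e-12))
  }
})

test_that("deterministic engine matches the microsimulation oracle in expectation", {
  co <- default_config$cohorts$C2
  trc <- run_horizon(co, tp_nyha23, cycles = 12)
  ms <- simulate_cohort(co, tp_nyha23, eff = NULL, costs = default_costs,
                        n_patients = 40000, cycles = 12, seed = 11,
                        settings = shipped_settings)
  s <- ms$summary[ms$summary$arm == "usual", ]
  expect_lt(abs(s$mean_admissions - total_admissions(trc)),
            3 * s$se_admissions)
  expect_lt(abs(s$mean_life_years -
                  life_years(trc, convention = "end", discount_rate = 0.03)),
            3 * s$se_life_years)
})
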