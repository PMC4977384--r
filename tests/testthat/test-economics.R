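# Discounting, TREAT expectation, per-cycle cost channels and accumulation.

test_that("discount factors follow the end-of-cycle conventions", {
  expect_equal(discount_factor(7, 0), 1.0)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(1, 0.03), 1.03^(-1 / 12))
  # annual granularity: year 1 undiscounted, year 2 discounted once
  expect_equal(discount_factor(1:12, 0.03, method = "annual"), rep(1, 12))
  expect_equal(discount_factor(13, 0.03, method = "annual"), 1 / 1.03)
  expect_equal(discount_factor(25, 0.03, method = "annual"), 1.03^-2)
})

test_that("expected TREAT cost prices true and false positives", {
  expect_equal(
    expected_treat_cost(0.106, efficacy_scenario(0.8, 0.8, 0, 0, 0),
                        default_costs),
    (0.8 * 0.106 + 0.2 * 0.894) * 187)  # = 49.29244
  perfect <- efficacy_scenario(1, 1, 0, 0, 0)
  expect_equal(expected_treat_cost(0, perfect, default_costs), 0)
  p <- c(0.05, 0.2, 0.9)
  expect_equal(expected_treat_cost(p, perfect, default_costs), 187 * p)
})

test_that("cycle costs split into the documented channels", {
  dead <- setNames(c(0, 0, 0, 0, 0, 1), chf_states())
  expect_equal(sum(cycle_cost("usual", dead, 0, tp_nyha23, base_scenario,
                              default_costs, cycle = 1)), 0)
  # fully alive usual-care cycle, no admissions, no discounting
  alive <- setNames(c(1, 0, 0, 0, 0, 0), chf_states())
  cs0 <- default_costs; cs0$annual_discount_rate <- 0
  cc <- cycle_cost("usual", alive, 0, tp_nyha23, base_scenario, cs0, cycle = 1)
  expect_equal(unname(cc["outpatient"] + cc["non_chf"]), 1700 / 12 + 10000 / 12)
  expect_equal(unname(cc[c("test", "treat", "admission")]), c(0, 0, 0))
  expect_error(cycle_cost("bogus", alive, 0, tp_nyha23, base_scenario,
                          default_costs, cycle = 1), "bogus")
})

test_that("an undetectable program yields no length-of-stay discount", {
  # SEN = 0 with per-detection LOS gating: admissions are billed in full
  blind <- efficacy_scenario(0, 1, 0, 0, 0.25)
  s <- modifyList(shipped_settings, list(los_gating = "sen"))
  alive <- setNames(c(0, 0, 1, 0, 0, 0), chf_states())
  cs0 <- default_costs; cs0$annual_discount_rate <- 0
  cc <- cycle_cost("telehealth", alive, 0.106, tp_nyha23, blind, cs0,
                   cycle = 1, settings = s)
  expect_equal(unname(cc["admission"]), 0.106 * 12000)
})

test_that("cost accumulation is linear and its breakdown sums per cycle", {
  co <- default_config$cohorts$C2
  trc <- run_horizon(co, tp_nyha23, cycles = 12)
  ct <- accumulate_costs(trc, "usual", tp_nyha23, base_scenario, default_costs,
                         shipped_settings)
  expect_equal(ct$per_cycle_cost,
               ct$admission + ct$outpatient + ct$non_chf + ct$test + ct$treat)
  expect_equal(cost_total(ct), sum(ct$per_cycle_cost))
  # zero schedule, and homogeneity of degree one in all prices
  expect_equal(cost_total(accumulate_costs(trc, "usual", tp_nyha23,
                                           base_scenario, zero_costs)), 0)
  doubled <- default_costs
  for (f in setdiff(names(doubled), "annual_discount_rate")) {
    doubled[[f]] <- doubled[[f]] * 2
  }
  expect_equal(cost_total(accumulate_costs(trc, "usual", tp_nyha23,
                                           base_scenario, doubled,
                                           shipped_settings)),
               2 * cost_total(ct))
})

test_that("telehealth total is affine in the monthly TEST fee", {
  co <- default_config$cohorts$C2
  tp_adj <- adjust_hazards(tp_nyha23,
                           effective_efficacy(base_scenario, "sen"))
  trc <- run_horizon(co, tp_adj, cycles = 24)
  total_at <- function(fee) {
    cost_total(accumulate_costs(trc, "telehealth", tp_nyha23, base_scenario,
                                set_monthly_fee(default_costs, fee),
                                shipped_settings))
  }
  slope_expected <- sum(
    chfmarkov:::cost_exposure(trc) *
      discount_factor(1:24, 0.03, method = shipped_settings$discount_method))
  fees <- c(0, 50, 220, 450)
  totals <- vapply(fees, total_at, numeric(1))
  fitted <- stats::lm(totals ~ fees)
  expect_equal(unname(stats::coef(fitted)["fees"]), slope_expected)
  expect_equal(unname(fitted$residuals), rep(0, 4), tolerance = 1e-9)
  # strictly increasing in the per-admission price too
  cs_hi <- default_costs; cs_hi$cost_per_admission <- 15000
  expect_gt(cost_total(accumulate_costs(trc, "telehealth", tp_nyha23,
                                        base_scenario, cs_hi,
                                        shipped_settings)),
            cost_total(accumulate_costs(trc, "telehealth", tp_nyha23,
                                        base_scenario, default_costs,
                                        shipped_settings)))
})

test_that("null efficacy and zero fees make the arms economically identical", {
  co <- default_config$cohorts$C2
  cs <- default_costs
  cs$monthly_install <- cs$monthly_monitoring <- cs$monthly_case_manager <- 0
  trc <- run_horizon(co, tp_nyha23, cycles = 24)
  u <- cost_total(accumulate_costs(trc, "usual", tp_nyha23, null_efficacy(), cs))
  t <- cost_total(accumulate_costs(trc, "telehealth", tp_nyha23,
                                   null_efficacy(), cs))
  expect_equal(t, u)
})
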