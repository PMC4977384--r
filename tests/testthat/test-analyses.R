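# Arm comparisons, sensitivity analyses, break-even solving, validation runs.

test_that("a null intervention with zero fees produces zero increments", {
  cs <- default_costs
  cs$monthly_install <- cs$monthly_monitoring <- cs$monthly_case_manager <- 0
  cmp <- compare_arms(default_config$cohorts$C2, null_efficacy(), cs,
                      tp_nyha23, horizon_months = 12)
  expect_equal(cmp$incremental$cost, 0)
  expect_equal(cmp$incremental$life_years, 0)
  expect_equal(cmp$incremental$admissions, 0)
})

test_that("tidy and glance expose the comparison as tibbles", {
  cmp <- compare_arms(default_config$cohorts$C2, base_scenario, default_costs,
                      tp_nyha23, horizon_months = 12,
                      settings = shipped_settings)
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$arm, c("usual", "telehealth", "incremental"))
  expect_equal(td$cost[2] - td$cost[1], td$cost[3])
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$d_cost, cmp$incremental$cost)
  expect_lt(gl$d_cost, 0)  # intermediate risk saves money over one year
})

test_that("telehealth never harms clinically under the shipped scenarios", {
  for (co in default_config$cohorts) {
    for (scen in default_config$scenarios) {
      cmp <- compare_arms(co, scen, default_costs, tp_nyha23,
                          horizon_months = 24, settings = shipped_settings)
      expect_gte(cmp$incremental$life_years, 0)
      expect_lte(cmp$incremental$admissions, 0)
    }
  }
})

test_that("the base-case table has one row per cohort and horizon", {
  tab <- basecase_table(default_config, horizons = c(12, 36))
  expect_equal(nrow(tab), 6)
  expect_equal(sort(unique(tab$cohort)), c("C1", "C2", "C3"))
  expect_error(basecase_table(default_config, cohorts = c("C1", "C9")),
               "C1, C2, C3")
})

test_that("one-way sweeps reproduce the base case at scale 1 and move monotonically", {
  co <- default_config$cohorts$C2
  base_cmp <- compare_arms(co, base_scenario, default_costs, tp_nyha23, 36,
                           shipped_settings)
  grid <- seq(0.5, 1, by = 0.1)
  sw_los <- sweep_efficacy(co, default_costs, tp_nyha23, 36, "los",
                           grid, base_scenario, shipped_settings)
  expect_equal(nrow(sw_los), 6)
  expect_equal(sw_los$d_cost[sw_los$scale == 1], base_cmp$incremental$cost)
  # more LOS effect -> more saving (d_cost nonincreasing in the scale)
  expect_true(all(diff(sw_los$d_cost) <= 1e-9))
  # less mortality effect -> more saving (d_cost nondecreasing in the scale)
  sw_mort <- sweep_efficacy(co, default_costs, tp_nyha23, 36, "mortality",
                            grid, base_scenario, shipped_settings)
  expect_true(all(diff(sw_mort$d_cost) >= -1e-9))
})

test_that("the two-way grid is affine in fee and admission cost", {
  co <- default_config$cohorts$C2
  g <- sensitivity_grid(co, base_scenario, tp_nyha23, 36,
                        monthly_fees = c(50, 150, 250),
                        admission_costs = c(6000, 8000, 10000),
                        costs = default_costs, settings = shipped_settings)
  expect_equal(nrow(g), 9)
  wide <- tidyr::pivot_wider(g, names_from = admission_cost,
                             values_from = d_cost)
  m <- as.matrix(wide[, -1])
  # equal steps in fee / admission cost give equal steps in d_cost
  expect_equal(m[3, ] - m[2, ], m[2, ] - m[1, ])
  expect_equal(m[, 3] - m[, 2], m[, 2] - m[, 1])
})

test_that("closed-form break-even agrees with root bracketing to a cent", {
  co <- default_config$cohorts$C2
  fee_star <- break_even_fee(co, base_scenario, default_costs, tp_nyha23, 12,
                             shipped_settings)
  d_cost_at <- function(fee) {
    compare_arms(co, base_scenario, set_monthly_fee(default_costs, fee),
                 tp_nyha23, 12, shipped_settings)$incremental$cost
  }
  root <- stats::uniroot(d_cost_at, c(0, 2000), tol = 1e-6)$root
  expect_lt(abs(fee_star - root), 0.01)
  expect_lt(abs(d_cost_at(fee_star)), 0.01)
})

test_that("break-even fees order with patient risk and report never cells", {
  tab <- break_even_table(default_config, horizons = c(12, 36, 60))
  expect_equal(nrow(tab), 27)
  by_cell <- tidyr::pivot_wider(tab, names_from = cohort, values_from = fee)
  fee0 <- function(x) ifelse(is.na(x), 0, x)  # "never" sorts below any fee
  expect_true(all(fee0(by_cell$C3) >= fee0(by_cell$C2)))
  expect_true(all(fee0(by_cell$C2) >= fee0(by_cell$C1)))
  # the low-risk cohort can never break even under the worst scenario
  worst_c1 <- tab[tab$cohort == "C1" & tab$scenario == "worst", ]
  expect_true(all(is.na(worst_c1$fee)))
})

test_that("lifetime run nearly extinguishes the cohort and prices a lifetime", {
  lt <- lifetime_validation(tp_nyha23, default_costs,
                            settings = shipped_settings)
  expect_gt(lt$fraction_dead, 0.9)
  expect_gt(lt$total_cost, 5e4)
  # without mortality, cost keeps growing with the horizon
  lt_short <- lifetime_validation(tp_zero, default_costs, cycles = 120,
                                  settings = shipped_settings)
  lt_long <- lifetime_validation(tp_zero, default_costs, cycles = 240,
                                 settings = shipped_settings)
  expect_gt(lt_long$total_cost, 1.5 * lt_short$total_cost)
})

test_that("national burden validates weights and scales linearly in population", {
  expect_equal(national_burden(tp_nyha23, default_costs, population = 0,
                               settings = shipped_settings)$total, 0)
  nb1 <- national_burden(tp_nyha23, default_costs, population = 1e6,
                         settings = shipped_settings)
  nb5 <- national_burden(tp_nyha23, default_costs, population = 5e6,
                         settings = shipped_settings)
  expect_equal(nb5$total, 5 * nb1$total)
  expect_error(national_burden(tp_nyha23, default_costs,
                               weights = c(0.5, 0.2, 0.1, 0.1, 0.05)),
               "weights")
})

test_that("savings rise to a mid-horizon peak for at-risk cohorts", {
  for (lbl in c("C2", "C3")) {
    co <- default_config$cohorts[[lbl]]
    saving_at <- function(h) {
      -compare_arms(co, base_scenario, default_costs, tp_nyha23, h,
                    shipped_settings)$incremental$cost
    }
    s12 <- saving_at(12); s36 <- saving_at(36); s60 <- saving_at(60)
    expect_gt(s36, s12)
    expect_gt(s36, s60)
  }
})

test_that("the savings curve accumulates the per-cycle arm difference", {
  co <- default_config$cohorts$C2
  cur <- savings_curve(co, base_scenario, default_costs, tp_nyha23, 36,
                       shipped_settings)
  expect_equal(nrow(cur), 36)
  cmp <- compare_arms(co, base_scenario, default_costs, tp_nyha23, 36,
                      shipped_settings)
  expect_equal(cur$cum_d_cost[36], cmp$incremental$cost)
  expect_equal(cur$cum_d_admissions[36], cmp$incremental$admissions)
})
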