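test_that("lifetime costs vanish when nobody uses care", {
  truth <- default_truth()
  p <- truth
  for (s in names(p$cost)) p$cost[[s]]$use[1L, ] <- -60
  mod <- scenario_model(p, scenario_spec("baseline"))
  lc <- lifetime_costs(mod, sex = 0, year = 2010)
  expect_equal(lc$expected_cost, rep(0, nrow(lc)), tolerance = 1e-15)
})

test_that("a single-state chain matches the hand-computed cost stream", {
  p <- toy_params(n_living = 1L, trans_rows = matrix(c(0.9, 0.1), 1),
                  year_levels = 2000L)
  p$cost$hospital$use[] <- 0                      # p_use = 0.5
  p$cost$hospital$mean[] <- 0; p$cost$hospital$mean[1, 1] <- log(1000)
  p$cost$hospital$use[4, 1] <- 0                  # no age effect
  mod <- scenario_model(p, scenario_spec("baseline"))
  lc <- lifetime_costs(mod, sex = 0, year = 2010)
  ## survival s_t = 0.9^t; each year contributes (s_t - 0.5 s_t 0.1) * 500
  s <- 0.9^(0:44)
  manual <- sum((s - 0.5 * s * 0.1) * 500)
  expect_equal(sum(lc$expected_cost), manual, tolerance = 1e-10)
  ## decomposition sums to the total per service
  truth <- default_truth()
  modt <- scenario_model(truth, scenario_spec("baseline"))
  lct <- lifetime_costs(modt, sex = 1, year = 2010)
  for (s in unique(lct$service)) {
    sub <- lct[lct$service == s, ]
    expect_equal(sum(sub$expected_cost[1:3]), sum(sub$expected_cost),
                 tolerance = 1e-12)
    expect_true(all(sub$expected_cost >= 0))
  }
})

test_that("aggregate expenditures are linear in population counts", {
  truth <- default_truth()
  mod <- scenario_model(truth, scenario_spec("baseline"))
  inp <- default_population_inputs()
  init1 <- init_population(inp$stock, model_state_shares(truth))
  inp2 <- default_population_inputs(stock_count = 200,
                                    entrant_count = 200)
  init2 <- init_population(inp2$stock, model_state_shares(truth))
  t1 <- project(init1, inp$entrants, mod, end_year = 2020)
  t2 <- project(init2, inp2$entrants, mod, end_year = 2020)
  s1 <- aggregate_expenditures(t1, mod, "homecare")
  s2 <- aggregate_expenditures(t2, mod, "homecare")
  expect_equal(s2$amount, 2 * s1$amount, tolerance = 1e-12)
  ## empty population, zero series
  init0 <- init_population(data.frame(age = 65, sex = 0, count = 0),
                           model_state_shares(truth))
  t0 <- project(init0, inp$entrants[0, ], mod, end_year = 2015)
  expect_equal(aggregate_expenditures(t0, mod, "ltc")$amount,
               rep(0, 6))
})

test_that("a lone cohort's aggregate stream equals its lifetime costs", {
  truth <- default_truth()
  mod <- scenario_model(truth, scenario_spec("baseline"))
  init0 <- init_population(data.frame(age = 65, sex = 1, count = 0),
                           model_state_shares(truth))
  ents <- data.frame(year = 2011, sex = 1, count = 500)
  traj <- project(init0, ents, mod, end_year = 2060)
  for (s in c("hospital", "ltc")) {
    ser <- aggregate_expenditures(traj, mod, s)
    lc <- lifetime_costs(mod, sex = 1, year = 2011, convention = "cohort",
                         services = s)
    expect_equal(sum(ser$amount), 500 * sum(lc$expected_cost),
                 tolerance = 1e-9)
  }
})

test_that("growth rates follow the geometric-mean definition", {
  flat <- data.frame(year = 2010:2050, amount = rep(7, 41))
  expect_equal(annual_growth_rate(flat), 0)
  doubling <- data.frame(year = 2010:2050,
                         amount = 3 * 2^((0:40) / 40))
  expect_equal(annual_growth_rate(doubling), (2^(1 / 40) - 1) * 100,
               tolerance = 1e-12)
  scaled <- doubling; scaled$amount <- scaled$amount * 1e6
  expect_equal(annual_growth_rate(scaled), annual_growth_rate(doubling))
  expect_error(annual_growth_rate(data.frame(year = 1:2,
                                             amount = c(0, 1))),
               "non-positive")
})

test_that("the report bundle writes all perspectives deterministically", {
  truth <- default_truth()
  specs <- list(baseline = scenario_spec("baseline"),
                "1o" = scenario_spec("1o"))
  dir1 <- withr::local_tempdir()
  ## uncalibrated non-baseline scenario is skipped with a warning
  expect_warning(report_bundle(specs, truth, dir1), "not calibrated")
  specs[["1o"]] <- calibrate(truth, specs[["1o"]], 0)
  specs[["1o"]] <- calibrate(truth, specs[["1o"]], 1)
  dir2 <- withr::local_tempdir()
  dir3 <- withr::local_tempdir()
  m2 <- report_bundle(specs, truth, dir2, seed = 7)
  report_bundle(specs, truth, dir3, seed = 7)
  for (f in c("lifetime_le_costs.csv", "pyramids.csv",
              "expenditure_series.csv", "growth_rates.csv"))
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir3, f)))
  series <- read.csv(file.path(dir2, "expenditure_series.csv"))
  expect_setequal(unique(series$scenario), c("baseline", "1o"))
  expect_setequal(unique(series$service), c("hospital", "homecare", "ltc"))
  growth <- read.csv(file.path(dir2, "growth_rates.csv"))
  expect_equal(nrow(growth), 6L)
  expect_equal(m2$scenarios$baseline$rates, "not-applicable")
})

test_that("longer lives under expansion raise lifetime LTC costs", {
  truth <- default_truth()
  base <- lifetime_costs(scenario_model(truth, scenario_spec("baseline")),
                         sex = 0, year = 2050)
  spec <- calibrate(truth, scenario_spec("1o"), 0)
  exp_lc <- lifetime_costs(scenario_model(truth, spec), sex = 0,
                           year = 2050)
  ltc_base <- sum(base$expected_cost[base$service == "ltc"])
  ltc_exp <- sum(exp_lc$expected_cost[exp_lc$service == "ltc"])
  expect_gt(ltc_exp, ltc_base)
})
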