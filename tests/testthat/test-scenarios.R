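test_that("the compounded multiplier follows (1-x)^(year-2010)", {
  expect_equal(compound_factor(0, 2035), 1)
  expect_equal(compound_factor(0.02, 2011), 0.98)
  expect_equal(compound_factor(0.02, 2050), 0.98^40)
  expect_error(compound_factor(1.2, 2020))
  expect_error(compound_factor(0.1, 2005))
})

test_that("expansion scales death and banks the mass on the diagonal", {
  row <- c(0.80, 0.10, 0.06, 0.04)
  expect_equal(apply_expansion(row, 1, 0.5), c(0.82, 0.10, 0.06, 0.02))
  expect_equal(apply_expansion(row, 1, 1), row)
  ## printed poor-row example: death 0.15 -> 0.09 at multiplier 0.6
  poor <- c(0.00, 0.04, 0.81, 0.15)
  adj <- apply_expansion(poor, 3, 0.6)
  expect_equal(adj[4], 0.09)
  expect_equal(adj[3], 0.87)
  expect_equal(adj[1:2], poor[1:2])
  expect_error(apply_expansion(c(0.5, 0.2, 0.1, 0.1), 1, 0.5),
               "probability vector")
})

test_that("compression improves good/moderate rows, never the poor row", {
  good <- c(0.87, 0.07, 0.04, 0.02)
  expect_equal(apply_compression(good, 1, 0.5),
               c(0.935, 0.035, 0.02, 0.01))
  expect_equal(apply_compression(good, 1, 1), good)
  poor <- c(0.00, 0.04, 0.81, 0.15)
  expect_identical(apply_compression(poor, 3, 0.5), poor)
})

test_that("dynamic equilibrium shifts mass toward moderate health", {
  good <- c(0.87, 0.07, 0.04, 0.02)
  ## printed scenario rows at multiplier 0.5 (good) and 0.8 (poor death)
  expect_equal(apply_dynamic(good, 1, 0.5, 1), c(0.87, 0.10, 0.02, 0.01))
  poor <- c(0.00, 0.04, 0.81, 0.15)
  expect_equal(apply_dynamic(poor, 3, 1, 0.8), c(0.00, 0.04, 0.84, 0.12))
  expect_equal(apply_dynamic(good, 1, 1, 1), good)
  expect_equal(apply_dynamic(poor, 3, 1, 1), poor)
})

test_that("every operator returns a stochastic row and only moves what it
          may", {
  set.seed(51)
  for (i in 1:200) {
    row <- as.vector(rmultinom(1, 1000, runif(4) + 0.05)) / 1000
    origin <- sample(1:3, 1)
    mult <- runif(1)
    for (op in list(function(r) apply_expansion(r, origin, mult),
                    function(r) apply_compression(r, origin, mult),
                    function(r) apply_dynamic(r, origin, mult,
                                              runif(1)))) {
      adj <- op(row)
      expect_equal(sum(adj), 1, tolerance = 1e-12)
      expect_true(all(adj >= 0))
    }
    ## expansion changes only the death entry and the diagonal
    adj <- apply_expansion(row, origin, mult)
    untouched <- setdiff(1:4, c(origin, 4))
    expect_identical(adj[untouched], row[untouched])
  }
})

test_that("initial profiles ramp linearly to the stated endpoints", {
  base <- c(0.66, 0.27, 0.06) / 0.99
  for (id in c("baseline", "1o", "2o", "3o"))
    expect_equal(initial_profile(scenario_spec(id), 2035, base), base)
  for (id in c("2+", "2++")) {
    expect_equal(initial_profile(scenario_spec(id), 2010, base), base)
    p50 <- initial_profile(scenario_spec(id), 2050, base)
    expect_equal(p50[1], 1)
    expect_equal(p50[2:3], c(0, 0))
    p30 <- initial_profile(scenario_spec(id), 2030, base)
    expect_equal(p30[1], (base[1] + 1) / 2)
    expect_equal(p30[2] / p30[3], base[2] / base[3])  # proportional rest
  }
  for (id in c("3+", "3++")) {
    p50 <- initial_profile(scenario_spec(id), 2050, base)
    expect_equal(p50[2], 0.45)
    expect_equal(sum(p50), 1)
    expect_equal(p50[1] / p50[3], base[1] / base[3])
  }
  expect_error(initial_profile(scenario_spec("2+"), 2030, c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("scenario rows reduce to baseline in 2010 and for baseline", {
  truth <- default_truth()
  spec <- scenario_spec("1o")
  spec$rates$male <- list(x = 0.02)
  mod <- scenario_model(truth, spec)
  base_row <- transition_row(truth, 2, ref_covs)
  expect_equal(scenario_transition_row(mod, 2, ref_covs, 2010), base_row)
  bmod <- scenario_model(truth, scenario_spec("baseline"))
  expect_equal(scenario_transition_row(bmod, 2, ref_covs, 2047), base_row)
  ## death probability non-increasing in year under expansion
  deaths <- vapply(2010:2050, function(y)
    scenario_transition_row(mod, 2, ref_covs, y)[4], numeric(1L))
  expect_true(all(diff(deaths) <= 0))
  ## death origin stays absorbing
  expect_equal(scenario_transition_row(mod, 4, ref_covs, 2040),
               c(0, 0, 0, 1))
})

test_that("life table conventions hold at the extremes", {
  ## immediate certain death: LE = half a year
  p <- toy_params(n_living = 2L, trans_rows = rbind(c(1e-12, 1e-12, 1),
                                                    c(1e-12, 1e-12, 1)))
  mod <- scenario_model(p, scenario_spec("baseline"))
  lt <- remaining_life_expectancy(mod, sex = 0, year = 2010)
  expect_equal(lt$total, 0.5, tolerance = 1e-6)
  expect_equal(remaining_life_expectancy(mod, sex = 0, year = 2010,
                                         half_year = FALSE)$total, 1,
               tolerance = 1e-6)
  ## zero mortality: LE = cap - 65
  q <- toy_params(n_living = 2L, trans_rows = rbind(c(0.9, 0.1, 1e-15),
                                                    c(0.1, 0.9, 1e-15)))
  modq <- scenario_model(q, scenario_spec("baseline"))
  expect_equal(remaining_life_expectancy(modq, 0, 2010)$total, 45,
               tolerance = 1e-8)
})

test_that("life table matches the absorbing-chain closed form", {
  rows <- rbind(c(0.75, 0.15, 0.05, 0.05),
                c(0.10, 0.65, 0.15, 0.10),
                c(0.02, 0.08, 0.70, 0.20))
  p <- toy_params(n_living = 3L, trans_rows = rows)
  mod <- scenario_model(p, scenario_spec("baseline"))
  lt <- remaining_life_expectancy(mod, sex = 0, year = 2010)
  ## rows are age-constant, so occupancy sums telescope:
  ## N = v0 (I + Q + ... + Q^44), years_m = N_m (1 - 0.5 d_m)
  v0 <- initial_state_probs(p, 65, 0)
  Q <- rows[, 1:3]
  N <- numeric(3); v <- v0
  for (t in 1:45) { N <- N + v; v <- drop(v %*% Q) }
  expect_equal(lt$by_state, N * (1 - 0.5 * rows[, 4]), tolerance = 1e-10)
  expect_equal(lt$total, sum(N * (1 - 0.5 * rows[, 4])),
               tolerance = 1e-10)
})

test_that("life expectancy increases monotonically in the expansion rate", {
  truth <- default_truth()
  les <- vapply(c(0, 0.005, 0.01, 0.02, 0.04, 0.08), function(x) {
    spec <- scenario_spec("1o")
    spec$rates$male <- list(x = x)
    remaining_life_expectancy(scenario_model(truth, spec), 0)$total
  }, numeric(1L))
  expect_true(all(diff(les) > 0))
})

test_that("calibration is a fixed point at the baseline target", {
  truth <- default_truth()
  base_le <- remaining_life_expectancy(
    scenario_model(truth, scenario_spec("baseline")), 0)$total
  spec <- calibrate(truth, scenario_spec("1o"), 0, target = base_le)
  expect_lt(spec$rates$male$x, 1e-5)
  expect_lt(abs(spec$rates$male$achieved_le - base_le), 0.005)
})

test_that("calibration reaches a +2 year target and reports iterations", {
  truth <- default_truth()
  base_le <- remaining_life_expectancy(
    scenario_model(truth, scenario_spec("baseline")), 0)$total
  spec <- calibrate(truth, scenario_spec("2o"), 0, target = base_le + 2)
  r <- spec$rates$male
  expect_lt(abs(r$achieved_le - (base_le + 2)), 0.005)
  expect_gt(r$x, 0)
  expect_gt(r$iterations, 5)
})

test_that("unreachable targets fail with the achievable range", {
  truth <- default_truth()
  expect_error(calibrate(truth, scenario_spec("1o"), 0, target = 46),
               "unreachable.*achievable range", perl = TRUE)
  expect_error(calibrate(truth, scenario_spec("baseline"), 0),
               "no adjustment rate")
})
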