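test_that("init_population allocates counts by shares", {
  shares_tab <- function(age, sex) c(0.66, 0.27, 0.06) / 0.99
  pop <- init_population(data.frame(age = 65, sex = 1, count = 1000),
                         shares_tab)
  expect_equal(unname(pop$counts["65", "female", ]),
               1000 * c(0.66, 0.27, 0.06) / 0.99, tolerance = 1e-12)
  expect_equal(round(unname(pop$counts["65", "female", ])),
               c(667, 273, 61))
  ## zero counts give an empty valid state
  empty <- init_population(data.frame(age = 70, sex = 0, count = 0),
                           shares_tab)
  expect_equal(total_alive(empty), 0)
  ## degenerate shares put everyone in good health
  all_good <- init_population(data.frame(age = 70, sex = 0, count = 10),
                              function(a, s) c(1, 0, 0))
  expect_equal(unname(all_good$counts["70", "male", ]), c(10, 0, 0))
  expect_error(init_population(data.frame(age = 70, sex = 0, count = 1),
                               function(a, s) c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("stepping shifts ages under identity transitions", {
  p <- toy_params(n_living = 3L)
  for (l in 1:3) { p$trans[[l]][1L, ] <- -60; p$trans[[l]][1L, l] <- 0 }
  mod <- scenario_model(p, scenario_spec("baseline"))
  pop <- init_population(data.frame(age = c(65, 70), sex = c(0, 0),
                                    count = c(10, 20)),
                         model_state_shares(p))
  nxt <- step_year(pop, mod)
  expect_equal(nxt$year, 2011L)
  expect_equal(nxt$counts["66", "male", ], pop$counts["65", "male", ],
               tolerance = 1e-12)
  expect_equal(nxt$counts["71", "male", ], pop$counts["70", "male", ],
               tolerance = 1e-12)
  expect_equal(sum(nxt$deaths_step), 0, tolerance = 1e-10)
})

test_that("certain death empties the population into deaths", {
  p <- toy_params(n_living = 2L, trans_rows = rbind(c(1e-12, 1e-12, 1),
                                                    c(1e-12, 1e-12, 1)))
  mod <- scenario_model(p, scenario_spec("baseline"))
  pop <- init_population(data.frame(age = 70, sex = 1, count = 50),
                         model_state_shares(p), n_living = 2L)
  nxt <- step_year(pop, mod)
  expect_equal(total_alive(nxt), 0, tolerance = 1e-8)
  expect_equal(sum(nxt$deaths_step), 50, tolerance = 1e-8)
})

test_that("two steps equal the two-year product matrix per cohort", {
  truth <- default_truth()
  mod <- scenario_model(truth, scenario_spec("baseline"))
  pop <- init_population(data.frame(age = 72, sex = 1, count = 100),
                         model_state_shares(truth))
  two <- step_year(step_year(pop, mod), mod)
  v0 <- pop$counts["72", "female", ]
  P1 <- t(vapply(1:3, function(l) transition_row(
    truth, l, list(sex = 1, partner = 1, age = 72, education = 2)),
    numeric(4)))[, 1:3]
  P2 <- t(vapply(1:3, function(l) transition_row(
    truth, l, list(sex = 1, partner = 1, age = 73, education = 2)),
    numeric(4)))[, 1:3]
  expect_equal(unname(two$counts["74", "female", ]),
               drop(v0 %*% P1 %*% P2), tolerance = 1e-12)
})

test_that("the yearly accounting identity holds along a projection", {
  truth <- default_truth()
  mod <- scenario_model(truth, scenario_spec("baseline"))
  inp <- default_population_inputs()
  traj <- cached("traj_baseline", function()
    project(init_population(inp$stock, model_state_shares(truth)),
            inp$entrants, mod))
  for (y in seq(2011, 2050, by = 7)) {
    alive1 <- total_alive(traj$states[[as.character(y)]])
    alive0 <- total_alive(traj$states[[as.character(y - 1)]])
    d <- sum(traj$states[[as.character(y)]]$deaths_step)
    ent <- sum(inp$entrants$count[inp$entrants$year == y])
    expect_equal(alive1, alive0 - d + ent, tolerance = 1e-9)
  }
  expect_true(all(vapply(traj$states, function(s) all(s$counts >= 0),
                         logical(1L))))
})

test_that("zero entrants and certain death give an empty population", {
  p <- toy_params(n_living = 2L, trans_rows = rbind(c(1e-12, 1e-12, 1),
                                                    c(1e-12, 1e-12, 1)))
  mod <- scenario_model(p, scenario_spec("baseline"))
  init <- init_population(data.frame(age = 70, sex = 0, count = 10),
                          model_state_shares(p), n_living = 2L)
  traj <- project(init, data.frame(year = integer(), sex = numeric(),
                                   count = numeric())[0, ], mod,
                  end_year = 2013)
  for (y in 2011:2013)
    expect_equal(total_alive(traj$states[[as.character(y)]]), 0,
                 tolerance = 1e-8)
})

test_that("a constant-inflow projection approaches a stationary profile", {
  truth <- default_truth()
  mod <- scenario_model(truth, scenario_spec("baseline"))
  init <- init_population(data.frame(age = 65, sex = 0, count = 100),
                          model_state_shares(truth))
  ents <- data.frame(year = 2011:2150, sex = 0, count = 100)
  traj <- project(init, ents, mod, end_year = 2150)
  a <- traj$states[["2149"]]$counts
  b <- traj$states[["2150"]]$counts
  expect_lt(max(abs(a - b)) / max(b), 1e-6)
})

test_that("trajectories export as long CSV with a provenance sidecar", {
  truth <- default_truth()
  mod <- scenario_model(truth, scenario_spec("baseline"))
  inp <- default_population_inputs()
  traj <- cached("traj_baseline", function()
    project(init_population(inp$stock, model_state_shares(truth)),
            inp$entrants, mod))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  long <- read.csv(path)
  expect_named(long, c("year", "sex", "age", "state", "persons"))
  expect_equal(sum(long$persons[long$year == 2030]),
               total_alive(traj$states[["2030"]]), tolerance = 1e-9)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$scenario, "baseline")
  expect_equal(side$base_year, 2010)
  expect_false(is.null(side$model_fingerprint))
})

test_that("pyramids partition the population and share the 2010 base", {
  truth <- default_truth()
  mod <- scenario_model(truth, scenario_spec("baseline"))
  inp <- default_population_inputs()
  traj <- cached("traj_baseline", function()
    project(init_population(inp$stock, model_state_shares(truth)),
            inp$entrants, mod))
  pyr <- pyramid(traj, 2050)
  expect_equal(sum(pyr$persons),
               total_alive(traj$states[["2050"]]), tolerance = 1e-9)
  raw <- pyramid(traj, 2030, bin_width = 1L)
  s <- traj$states[["2030"]]
  expect_equal(sum(raw$persons[raw$age_lo == 70]),
               sum(s$counts["70", , ]), tolerance = 1e-12)
  expect_error(pyramid(traj, 2051), "not in trajectory")
  ## the 2010 pyramid is scenario-invariant
  spec1 <- calibrate(truth, scenario_spec("1o"), 0)
  spec1 <- calibrate(truth, spec1, 1)
  traj1 <- project(init_population(inp$stock, model_state_shares(truth)),
                   inp$entrants, scenario_model(truth, spec1),
                   end_year = 2012)
  expect_equal(pyramid(traj1, 2010), pyramid(traj, 2010))
})
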