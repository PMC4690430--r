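test_that("the default truth has the required structural orderings", {
  truth <- default_truth()
  ## severity strictly increasing good -> moderate -> poor per indicator
  prof <- standardized_state_profiles(truth)
  for (r in seq_len(nrow(prof)))
    expect_true(all(diff(as.numeric(prof[r, -1L])) > 0),
                label = paste("severity ordering for", prof$indicator[r]))
  ## death hazard increasing in state at reference covariates
  death_p <- vapply(1:3, function(l)
    transition_row(truth, l, ref_covs)[4], numeric(1L))
  expect_true(all(diff(death_p) > 0))
  ## death is absorbing
  expect_equal(transition_row(truth, 4, ref_covs), c(0, 0, 0, 1))
})

test_that("different seeds give the same shape but different values", {
  t1 <- default_truth(1)
  t2 <- make_default_truth(2)
  expect_identical(lapply(t1$trans, dim), lapply(t2$trans, dim))
  expect_identical(t1$indicators, t2$indicators)
  expect_false(identical(t1$trans, t2$trans))
  expect_false(identical(t1$emission, t2$emission))
  ## same seed reproduces bit-identically
  expect_identical(make_default_truth(1), make_default_truth(1))
})

test_that("simulate_individual respects forced absorption and identity", {
  ## certain death from every state: exactly one record, dead
  p <- toy_params(n_living = 2L)
  for (l in 1:2) {
    p$trans[[l]][1L, ] <- c(-50, -50, 50)  # death logit dominates
    p$trans[[l]][1L, l] <- 0
  }
  set.seed(1)
  rec <- simulate_individual(p, list(sex = 0, partner = 1, age = 70,
                                     education = 2, entry_year = 2000),
                             horizon = 5)
  expect_equal(nrow(rec), 2L)  # one living record, then the death record
  expect_equal(rec$vital_status, c("alive", "dead"))
  ## identity transitions, forced start in state 1: all records in state 1
  q <- toy_params(n_living = 2L, init_shares = c(1 - 1e-12, 1e-12))
  for (l in 1:2) { q$trans[[l]][1L, ] <- -50; q$trans[[l]][1L, l] <- 0 }
  set.seed(2)
  rec <- simulate_individual(q, list(sex = 1, partner = 0, age = 60,
                                     education = 1, entry_year = 2000),
                             horizon = 8)
  expect_equal(nrow(rec), 8L)
  expect_true(all(rec$state == 1L))
  expect_true(all(rec$vital_status == "alive"))
})

test_that("invalid profiles are rejected with a message", {
  truth <- default_truth()
  expect_error(simulate_individual(truth, list(sex = 0, partner = 1,
                                               age = 40, education = 2,
                                               entry_year = 1995), 3),
               "age")
  expect_error(simulate_individual(truth, list(sex = 2, partner = 1,
                                               age = 70, education = 2,
                                               entry_year = 1995), 3),
               "sex")
  expect_error(simulate_individual(truth, list(sex = 0, age = 70,
                                               entry_year = 1995), 3),
               "missing fields")
})

test_that("empirical one-year transitions match the model probabilities", {
  truth <- default_truth()
  ## force the initial state to moderate so the first transition is known
  p <- truth
  p$init[1L, ] <- c(0, 50, 0)
  profile <- list(sex = 0, partner = 1, age = 75, education = 2,
                  entry_year = 1995)
  set.seed(31)
  n <- 10000
  dest <- integer(n)
  for (i in seq_len(n)) {
    rec <- simulate_individual(p, profile, horizon = 2)
    dest[i] <- if (nrow(rec) == 2L) rec$state[2L] else rec$state[1L]
  }
  expected <- transition_row(truth, 2, profile)
  emp <- tabulate(dest, nbins = 4) / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(emp - expected) <= 3 * se + 1e-12))
})

test_that("simulate_panel handles the empty case and is reproducible", {
  truth <- default_truth()
  p0 <- simulate_panel(truth, 0, seed = 5)
  expect_equal(nrow(p0), 0L)
  expect_equal(panel_schedule(p0)$survey_years, seq(1995, 2007, 3))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(simulate_panel(truth, 60, seed = 9), f1)
  write_panel(simulate_panel(truth, 60, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the observation schedule masks indicators and registry costs", {
  truth <- default_truth()
  panel <- small_panel(n = 200, seed = 7)
  df <- as.data.frame(panel)
  sched <- panel_schedule(panel)
  alive <- df$vital_status == "alive"
  has_ind <- !is.na(df$y1)
  ## indicators only in survey years (death years carry none by design)
  expect_true(all(df$year[has_ind] %in% sched$survey_years))
  ## roughly one wave in three plus terminal observations
  frac <- mean(has_ind[alive])
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.50)
  ## per-individual gaps between indicator observations are multiples of 3
  gaps <- unlist(tapply(df$year[has_ind], df$id[has_ind],
                        function(y) diff(sort(y))))
  expect_true(all(gaps %% 3 == 0))
  ## LTC costs unobserved before the window, observed inside it when alive
  expect_true(all(is.na(df$cost_ltc[df$year < 2004])))
  expect_true(all(!is.na(df$cost_ltc[alive & df$year >= 2004])))
  ## hospital costs observed in every living year
  expect_true(all(!is.na(df$cost_hospital[alive])))
})

test_that("an identity schedule returns the panel unchanged", {
  truth <- default_truth()
  raw <- simulate_panel(truth, 40, seed = 3, apply_schedule = FALSE)
  full <- apply_observation_schedule(raw, survey_interval = 1,
                                     registry_windows = list(
                                       hospital = c(1995, 2007),
                                       homecare = c(1995, 2007),
                                       ltc = c(1995, 2007)))
  expect_equal(as.data.frame(full), as.data.frame(raw)[names(full)],
               ignore_attr = TRUE)
  expect_error(apply_observation_schedule(raw, 3,
                                          list(ltc = c(1990, 2007))),
               "outside the panel years")
})

test_that("no records exist after death and categories stay in range", {
  df <- as.data.frame(small_panel(n = 200, seed = 7))
  deaths <- df[df$vital_status == "dead", ]
  last <- tapply(df$year, df$id, max)
  expect_true(all(deaths$year == last[as.character(deaths$id)]))
  scheme <- indicator_scheme()
  for (j in seq_along(scheme)) {
    y <- df[[paste0("y", j)]]
    expect_true(all(is.na(y) | (y >= 1 & y <= scheme[[j]])))
  }
  expect_true(all(is.na(df$cost_hospital) | df$cost_hospital >= 0))
})

test_that("panels round-trip through CSV and malformed files are rejected", {
  panel <- small_panel(n = 150, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(as.data.frame(back), as.data.frame(panel),
               tolerance = 1e-12)
  expect_equal(panel_schedule(back)$survey_years,
               panel_schedule(panel)$survey_years)
  expect_equal(panel_schedule(back)$windows$ltc,
               panel_schedule(panel)$windows$ltc)

  lines <- readLines(path)
  hdr <- grep("^id,", lines)
  ## negative cost
  bad <- lines
  row1 <- strsplit(bad[hdr + 1L], ",")[[1]]
  row1[14] <- "-10"
  bad[hdr + 1L] <- paste(row1, collapse = ",")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, f)
  expect_error(read_panel(f), "negative cost at row 1, column cost_hospital")
  ## duplicated individual-year key
  bad <- append(lines, lines[hdr + 1L], after = hdr + 1L)
  writeLines(bad, f)
  expect_error(read_panel(f), "duplicated individual-year key")
  ## not a panel file at all
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_panel(f), "not a healthmarkov panel file")
})

test_that("occupancy in a large panel matches the chain's evolution", {
  truth <- default_truth()
  raw <- simulate_panel(truth, 1500, seed = 17, apply_schedule = FALSE,
                        keep_latent = TRUE,
                        design = panel_design(refresh_year = NA))
  df <- as.data.frame(raw)
  firsts <- df[!duplicated(df$id), ]
  ## analytic occupancy at year 3: propagate each individual's initial
  ## distribution through their covariate-specific transition matrices
  year3 <- df[df$year == 1998, ]
  pred <- matrix(0, nrow(firsts), 4)
  for (i in seq_len(nrow(firsts))) {
    v <- c(initial_state_probs(truth, firsts$age[i], firsts$sex[i]), 0)
    for (t in 0:2) {
      covs <- list(sex = firsts$sex[i], partner = firsts$partner[i],
                   age = firsts$age[i] + t, education = firsts$education[i])
      P <- rbind(t(vapply(1:3, function(l)
        transition_row(truth, l, covs), numeric(4))), c(0, 0, 0, 1))
      v <- drop(v %*% P)
    }
    pred[i, ] <- v
  }
  expected <- colMeans(pred)
  emp <- c(tabulate(year3$state[year3$vital_status == "alive"], 3),
           sum(df$vital_status == "dead" & df$year <= 1998)) /
    nrow(firsts)
  se <- sqrt(expected * (1 - expected) / nrow(firsts))
  expect_true(all(abs(emp - expected) <= 3 * se + 1e-12))
})
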