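## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

default_truth <- function(seed = 1L) {
  cached(paste0("truth_", seed), function() make_default_truth(seed))
}

small_panel <- function(n = 150L, seed = 7L) {
  cached(paste0("panel_", n, "_", seed), function()
    simulate_panel(default_truth(), n, seed = seed))
}

ref_covs <- list(sex = 0, partner = 1, age = 75, education = 2)

## A minimal hand-set parameter object: arbitrary living-state count, two
## indicators (3 and 2 categories), optionally a hospital cost model, no
## covariate effects unless supplied. Useful for closed-form checks.
toy_params <- function(n_living = 2L, trans_rows = NULL, init_shares = NULL,
                       with_cost = TRUE, year_levels = 2000:2002,
                       emission_slopes = seq(-1, 1,
                                             length.out = n_living)) {
  M <- n_living + 1L
  if (is.null(trans_rows)) {
    trans_rows <- matrix(0.1 / (M - 1L), n_living, M)
    diag(trans_rows) <- 0
    trans_rows[, M] <- 0.1
    for (l in seq_len(n_living))
      trans_rows[l, l] <- 1 - sum(trans_rows[l, -l])
  }
  trans <- lapply(seq_len(n_living), function(l) {
    B <- matrix(0, 5L, M)
    B[1L, ] <- log(pmax(trans_rows[l, ], 1e-12) / trans_rows[l, l])
    B[1L, l] <- 0
    rownames(B) <- c("intercept", "sex", "partner", "age_dec", "educ")
    B
  })
  init <- matrix(0, 3L, n_living,
                 dimnames = list(c("intercept", "age_dec", "sex"), NULL))
  if (!is.null(init_shares))
    init[1L, ] <- log(init_shares / init_shares[1L])
  scheme <- c(ind1 = 3L, ind2 = 2L)
  emission <- lapply(scheme, function(K)
    outer(0:(K - 1L), emission_slopes))
  cost <- list()
  if (with_cost) {
    n_cov <- 5L + length(year_levels) - 1L
    use <- matrix(0, n_cov, n_living)
    use[1L, ] <- seq(-1, 0.5, length.out = n_living)
    mean_ <- matrix(0, n_cov, n_living)
    mean_[1L, ] <- log(seq(1000, 3000, length.out = n_living))
    cost <- list(hospital = list(use = use, mean = mean_, shape = 1.3))
  }
  latent_params(n_living = n_living, indicators = scheme, init = init,
                trans = trans, emission = emission, cost = cost,
                year_levels = year_levels)
}

## Random parameter set + record sequence for likelihood oracle checks.
random_params <- function(n_living) {
  M <- n_living + 1L
  trans <- lapply(seq_len(n_living), function(l) {
    B <- matrix(rnorm(5L * M, sd = 0.4), 5L, M)
    B[, l] <- 0
    rownames(B) <- c("intercept", "sex", "partner", "age_dec", "educ")
    B
  })
  scheme <- c(ind1 = 3L, ind2 = 2L)
  emission <- lapply(scheme, function(K) {
    E <- matrix(rnorm(K * n_living, sd = 1), K, n_living)
    sweep(E, 2L, E[1L, ], "-")
  })
  init <- matrix(rnorm(3L * n_living, sd = 0.5), 3L, n_living)
  init[, 1L] <- 0
  rownames(init) <- c("intercept", "age_dec", "sex")
  n_cov <- 5L + 2L
  use <- matrix(rnorm(n_cov * n_living, sd = 0.3), n_cov, n_living)
  mean_ <- matrix(rnorm(n_cov * n_living, sd = 0.2), n_cov, n_living)
  mean_[1L, ] <- mean_[1L, ] + log(800)
  latent_params(n_living = n_living, indicators = scheme, init = init,
                trans = trans, emission = emission,
                cost = list(hospital = list(use = use, mean = mean_,
                                            shape = runif(1, 0.8, 2))),
                year_levels = 2000:2002)
}

random_records <- function(params, T_len, dies = FALSE) {
  scheme <- params$indicators
  age0 <- sample(60:90, 1L)
  df <- data.frame(
    id = 1L, year = 2000L + seq_len(T_len) - 1L,
    sex = sample(0:1, 1L), partner = sample(0:1, 1L),
    age = age0 + seq_len(T_len) - 1L,
    education = sample(1:3, 1L))
  for (j in seq_along(scheme)) {
    y <- sample.int(scheme[[j]], T_len, replace = TRUE)
    y[runif(T_len) < 0.5] <- NA
    df[[paste0("y", j)]] <- y
  }
  cost <- round(rgamma(T_len, 1.5, rate = 1.5 / 900), 2)
  cost[runif(T_len) < 0.4] <- 0
  cost[runif(T_len) < 0.3] <- NA
  df$cost_hospital <- cost
  df$cost_homecare <- NA_real_
  df$cost_ltc <- NA_real_
  df$vital_status <- "alive"
  if (dies) {
    df$vital_status[T_len] <- "dead"
    for (j in seq_along(scheme)) df[[paste0("y", j)]][T_len] <- NA
    df$cost_hospital[T_len] <- NA
  }
  df
}
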