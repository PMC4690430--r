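#' Default ground-truth parameter set for simulation studies
#'
#' Builds a complete `latent_params` object with three living states (good,
#' moderate, poor) plus death, shaped after the qualitative structure of the
#' estimated model: expected indicator severity strictly increases from good
#' to poor for every indicator, state-specific death hazards increase from
#' good to poor, and expected costs of all three services increase from good
#' to poor at working reference covariates. At the reference profile (men
#' aged 75, with partner, middle education) the living transition rows equal
#' the baseline transition matrix used throughout the scenario machinery
#' (good: 0.87/0.07/0.04/0.02; moderate: ~0/0.87/0.10/0.03; poor:
#' ~0/0.04/0.81/0.15), and the initial-state model at age 65 for men gives
#' living shares close to 2/3, 0.27 and 0.06.
#'
#' The seed perturbs all intercepts slightly (keeping the structural
#' orderings intact by construction), so different seeds give distinct but
#' equally shaped truths.
#'
#' @param seed Integer seed.
#' @param year_levels Panel calendar years (first year is the cost models'
#'   reference category).
#' @return A `latent_params` object with all three service cost models.
#' @export
make_default_truth <- function(seed = 1L, year_levels = 1995:2007) {
  rng <- local_rng(seed)

  ## --- transitions: intercepts anchored to the baseline matrix at the
  ## reference profile (male, partner, age 75, education 2)
  base_rows <- rbind(
    good     = c(0.870, 0.070, 0.040, 0.020),
    moderate = c(0.002, 0.868, 0.100, 0.030),
    poor     = c(0.002, 0.040, 0.808, 0.150)
  )
  trans <- vector("list", 3L)
  ## covariate effects per origin; columns good/moderate/poor/death.
  ## Death logit rises ~0.9 per decade; women and partnered individuals have
  ## lower mortality; education shifts transitions toward better states.
  cov_effects <- list(
    rbind(sex     = c(0, 0.00, -0.05, -0.50),
          partner = c(0, 0.00,  0.00, -0.10),
          age_dec = c(0, 0.35,  0.55,  0.85),
          educ    = c(0, -0.05, -0.08, -0.08)),
    rbind(sex     = c(0.00, 0, -0.05, -0.50),
          partner = c(0.00, 0,  0.00, -0.10),
          age_dec = c(-0.20, 0, 0.45,  0.85),
          educ    = c(0.05, 0, -0.08, -0.08)),
    rbind(sex     = c(0.00, 0.00, 0, -0.50),
          partner = c(0.00, 0.00, 0, -0.10),
          age_dec = c(-0.20, -0.20, 0, 0.70),
          educ    = c(0.05, 0.05, 0, -0.05))
  )
  for (l in 1:3) {
    ic <- log(base_rows[l, ] / base_rows[l, l])
    jit <- rng$norm(4L, sd = 0.03)
    jit[l] <- 0
    B <- rbind(intercept = ic + jit, cov_effects[[l]])
    rownames(B) <- c("intercept", "sex", "partner", "age_dec", "educ")
    trans[[l]] <- B
  }

  ## --- initial-state model: anchored so men at 65 have living shares
  ## (0.66, 0.27, 0.06) (normalized); health at entry worsens with age.
  age_slope <- c(0, 0.35, 0.80)
  target65 <- c(0.66, 0.27, 0.06) / 0.99
  ic <- log(target65 / target65[1L]) + age_slope  # shift to age-75 center
  ic <- ic + c(0, rng$norm(2L, sd = 0.02))
  init <- rbind(intercept = ic, age_dec = age_slope,
                sex = c(0, 0.10, 0.15))
  init[, 1L] <- 0

  ## --- indicator emissions: linear-in-category logits whose slope is
  ## solved so each state hits an indicator-specific target severity
  ## (standardized expected outcome in [0,1]). Targets follow the estimated
  ## state profiles: good health is near the best outcome on everything;
  ## moderate health pairs a high chronic-disease probability with mild
  ## disability and little depression or cognitive impairment; poor health
  ## is severe on disability, depression and cognition while self-perceived
  ## health is only slightly worse than in moderate health.
  scheme <- indicator_scheme()
  sev_targets <- rbind(           # rows: good, moderate, poor
    sph         = c(0.15, 0.40, 0.52),
    mobility    = c(0.10, 0.30, 0.80),
    performance = c(0.10, 0.30, 0.75),
    gali        = c(0.10, 0.35, 0.80),
    chronic     = c(0.15, 0.75, 0.85),
    depression  = c(0.08, 0.18, 0.65),
    cognition   = c(0.05, 0.12, 0.70)
  )
  severity_of_slope <- function(a, K) {
    p <- softmax_vec(a * (0:(K - 1L)))
    sum(p * (0:(K - 1L))) / (K - 1L)
  }
  emission <- lapply(seq_along(scheme), function(j) {
    K <- scheme[[j]]
    tgt <- sev_targets[names(scheme)[j], ]
    tgt <- pmin(0.97, pmax(0.03, tgt + (rng$unif(3L) - 0.5) * 0.04))
    tgt <- sort(tgt)  # severity ordering good < moderate < poor
    slopes <- vapply(tgt, function(s)
      uniroot(function(a) severity_of_slope(a, K) - s, c(-12, 12),
              tol = 1e-10)$root, numeric(1L))
    E <- outer(0:(K - 1L), slopes)
    E[1L, ] <- 0
    E
  })
  names(emission) <- names(scheme)

  ## --- two-part cost models; intercepts per state, zero calendar effects.
  ## Amounts are abstract cost units with magnitudes in the range of annual
  ## per-person costs of the three services.
  n_cov <- 5L + length(year_levels) - 1L
  cost_block <- function(use_p, mu, use_cov, mean_cov, shape) {
    use <- matrix(0, n_cov, 3L)
    mean_ <- matrix(0, n_cov, 3L)
    use[1L, ] <- log(use_p / (1 - use_p)) + rng$norm(3L, sd = 0.05)
    mean_[1L, ] <- log(mu) + rng$norm(3L, sd = 0.05)
    use[2:5, ] <- use_cov
    mean_[2:5, ] <- mean_cov
    list(use = use, mean = mean_, shape = shape)
  }
  cov4 <- function(sex, partner, age_dec, educ)
    matrix(rep(c(sex, partner, age_dec, educ), 3L), nrow = 4L)
  cost <- list(
    hospital = cost_block(c(0.15, 0.35, 0.60), c(2000, 4000, 7000),
                          cov4(0.00, -0.05, 0.45, -0.05),
                          cov4(-0.05, 0.00, 0.15, -0.05), shape = 1.2),
    homecare = cost_block(c(0.05, 0.25, 0.55), c(1500, 3000, 6000),
                          cov4(0.50, -0.20, 0.80, -0.05),
                          cov4(0.10, 0.00, 0.25, 0.00), shape = 1.0),
    ltc      = cost_block(c(0.010, 0.070, 0.40), c(8000, 15000, 25000),
                          cov4(0.30, -0.30, 1.00, -0.05),
                          cov4(0.10, 0.00, 0.20, 0.00), shape = 1.5)
  )

  latent_params(n_living = 3L, indicators = scheme, init = init,
                trans = trans, emission = emission, cost = cost,
                year_levels = year_levels)
}

## Seeded RNG stream that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- f(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(norm = with_state(function(n, sd = 1) rnorm(n, sd = sd)),
       unif = with_state(runif),
       eval = with_state(function(expr_fun) expr_fun()))
}
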