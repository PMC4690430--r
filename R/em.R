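## Weighted multinomial logit by Newton-Raphson with step halving.
## X: n x p design; W: n x K non-negative case weights per outcome;
## ref: reference outcome (coefficients fixed at zero).
wmultinom_fit <- function(X, W, ref = 1L, beta0 = NULL, tol = 1e-10,
                          max_iter = 200L) {
  p <- ncol(X); K <- ncol(W)
  free <- setdiff(seq_len(K), ref)
  beta <- if (is.null(beta0)) matrix(0, p, K) else beta0
  wtot <- rowSums(W)
  keep <- wtot > 0
  Xk <- X[keep, , drop = FALSE]
  Wk <- W[keep, , drop = FALSE]
  wtotk <- wtot[keep]
  ll_fun <- function(b) {
    P <- softmax_rows(Xk %*% b)
    sum(Wk * log(pmax(P, 1e-300)))
  }
  ll <- ll_fun(beta)
  nf <- length(free)
  for (iter in seq_len(max_iter)) {
    P <- softmax_rows(Xk %*% beta)
    g <- numeric(p * nf)
    H <- matrix(0, p * nf, p * nf)
    for (ai in seq_len(nf)) {
      a <- free[ai]
      ia <- (ai - 1L) * p + seq_len(p)
      g[ia] <- crossprod(Xk, Wk[, a] - wtotk * P[, a])
      for (bi in ai:nf) {
        b <- free[bi]
        wab <- wtotk * (P[, a] * ((a == b) - P[, b]))
        Hab <- crossprod(Xk, Xk * wab)
        ib <- (bi - 1L) * p + seq_len(p)
        H[ia, ib] <- Hab
        H[ib, ia] <- t(Hab)
      }
    }
    if (max(abs(g)) < tol * max(1, sum(wtotk))) break
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), g),
                     error = function(e) g / max(1, max(abs(diag(H)))))
    lam <- 1
    repeat {
      beta_new <- beta
      for (ai in seq_len(nf))
        beta_new[, free[ai]] <- beta[, free[ai]] +
          lam * step[(ai - 1L) * p + seq_len(p)]
      ll_new <- ll_fun(beta_new)
      if (ll_new >= ll - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    done <- abs(ll_new - ll) < 1e-12 * max(1, abs(ll))
    beta <- beta_new
    ll <- ll_new
    if (done) break
  }
  beta[, ref] <- 0
  beta
}

## ML estimate of the Gamma shape given fitted means: solves
## log(nu) - digamma(nu) = mean_w(c/mu - log(c/mu)) - 1.
gamma_shape_ml <- function(cost, mu, w) {
  rhs <- sum(w * (cost / mu - log(cost / mu))) / sum(w) - 1
  if (rhs <= 1e-12) return(1e6)
  f <- function(lnu) log(exp(lnu)) - digamma(exp(lnu)) - rhs
  exp(uniroot(f, c(log(1e-4), log(1e6)), tol = 1e-12)$root)
}

## Weighted GLM with graduated fallback: if the full design is inestimable
## with the available weight mass (sparse states on short registry
## windows), retry on the base covariates only, then intercept-only.
glm_weighted_safe <- function(X, y, w, family, start = NULL) {
  ctrl <- list(epsilon = 1e-12, maxit = 200L, trace = FALSE)
  for (cols in list(seq_len(ncol(X)), seq_len(min(5L, ncol(X))), 1L)) {
    fit <- tryCatch(suppressWarnings(
      glm.fit(X[, cols, drop = FALSE], y, weights = w, family = family,
              start = start[cols], control = ctrl)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0  # aliased columns pinned to the reference level
      if (all(is.finite(cf)) && max(abs(cf)) < 1e4) {
        coefs <- numeric(ncol(X))
        coefs[cols] <- cf
        return(list(coefficients = coefs,
                    fitted.values = fit$fitted.values))
      }
    }
    start <- NULL
  }
  stop("weighted GLM failed even for the intercept-only model")
}

## Weighted two-part fit for one service and one state.
fit_two_part_state <- function(X, cost, w, start_use = NULL,
                               start_mean = NULL) {
  keep <- w > 1e-12 & !is.na(cost)
  Xk <- X[keep, , drop = FALSE]
  ck <- cost[keep]
  wk <- w[keep]
  use_fit <- glm_weighted_safe(Xk, as.numeric(ck > 0), wk,
                               stats::quasibinomial(), start = start_use)
  pos <- ck > 0
  mean_fit <- glm_weighted_safe(Xk[pos, , drop = FALSE], ck[pos],
                                pmax(wk[pos], 1e-10),
                                Gamma(link = "log"), start = start_mean)
  list(use = use_fit$coefficients, mean = mean_fit$coefficients,
       mu = mean_fit$fitted.values, cost = ck[pos], w = wk[pos])
}

## One full M-step. posterior: result of e_step(); df: panel records.
m_step <- function(params, df, posterior, services = "hospital") {
  Ml <- params$n_living
  M <- params$n_states
  gamma <- posterior$gamma
  xi <- posterior$xi
  idx <- posterior$index

  ## initial-state logit (age, sex at first observation)
  firsts <- df[idx$starts, ]
  X0 <- design_init(firsts$age, firsts$sex)
  W0 <- gamma[idx$starts, seq_len(Ml), drop = FALSE]
  init <- wmultinom_fit(X0, W0, ref = 1L, beta0 = params$init)
  dimnames(init) <- dimnames(params$init)

  ## transition logits, one per living origin
  later <- which(!idx$first)
  prev <- df[later - 1L, ]
  Xt <- design_trans(prev$sex, prev$partner, prev$age, prev$education)
  trans <- params$trans
  for (l in seq_len(Ml)) {
    Wl <- t(xi[l, , later])
    trans[[l]] <- wmultinom_fit(Xt, Wl, ref = l, beta0 = params$trans[[l]])
    dimnames(trans[[l]]) <- dimnames(params$trans[[l]])
  }

  ## indicator intercepts: posterior-weighted category frequencies
  emission <- params$emission
  for (j in seq_along(params$indicators)) {
    y <- df[[paste0("y", j)]]
    obs <- !is.na(y)
    K <- params$indicators[[j]]
    for (m in seq_len(Ml)) {
      cnt <- vapply(seq_len(K), function(k)
        sum(gamma[obs & y == k, m]), numeric(1L)) + 1e-8
      emission[[j]][, m] <- log(cnt / cnt[1L])
    }
    emission[[j]][1L, ] <- 0
  }

  ## two-part cost models for jointly fitted services
  cost <- params$cost
  if (length(services)) {
    Xc <- design_cost(df$sex, df$partner, df$age, df$education, df$year,
                      params$year_levels)
    for (s in services) {
      cs <- cost[[s]]
      allmu <- list()
      for (m in seq_len(Ml)) {
        fit <- fit_two_part_state(Xc, df[[paste0("cost_", s)]], gamma[, m],
                                  start_use = cs$use[, m],
                                  start_mean = cs$mean[, m])
        cs$use[, m] <- fit$use
        cs$mean[, m] <- fit$mean
        allmu[[m]] <- fit
      }
      cs$shape <- gamma_shape_ml(
        unlist(lapply(allmu, `[[`, "cost")),
        unlist(lapply(allmu, `[[`, "mu")),
        unlist(lapply(allmu, `[[`, "w")))
      cost[[s]] <- cs
    }
  }

  latent_params(n_living = Ml, indicators = params$indicators, init = init,
                trans = trans, emission = emission, cost = cost,
                year_levels = params$year_levels)
}

## Severity-based initialization: per-record mean standardized indicator
## score, partitioned by k-means into n_living groups ordered by severity,
## turned into soft posteriors, then one M-step.
init_from_severity <- function(panel, n_living, year_levels, scheme,
                               jitter = 0) {
  df <- as.data.frame(panel)
  sev <- record_severity(df, scheme)
  ind_mean <- tapply(sev, df$id, function(x) mean(x, na.rm = TRUE))
  fill <- ind_mean[as.character(df$id)]
  fill[is.nan(fill)] <- mean(sev, na.rm = TRUE)
  sev[is.na(sev)] <- fill[is.na(sev)]
  if (jitter > 0) sev <- sev + rnorm(length(sev), sd = jitter)
  km <- kmeans(sev, centers = n_living, nstart = 5L)
  lab <- order(order(km$centers))[km$cluster]  # 1 = best health

  M <- n_living + 1L
  gamma <- matrix(0.1 / (M - 1L), nrow(df), M)
  gamma[cbind(seq_len(nrow(df)), lab)] <- 0.9
  dead <- df$vital_status == "dead"
  gamma[dead, ] <- 0
  gamma[dead, M] <- 1
  idx <- panel_index(df)
  gamma[idx$starts, M] <- 0
  gamma[idx$starts, ] <- gamma[idx$starts, , drop = FALSE] /
    rowSums(gamma[idx$starts, , drop = FALSE])
  xi <- array(0, c(M, M, nrow(df)))
  later <- which(!idx$first)
  for (r in later) xi[, , r] <- outer(gamma[r - 1L, ], gamma[r, ])
  posterior <- list(gamma = gamma, xi = xi, index = idx)

  blank <- blank_params(n_living, scheme, year_levels)
  m_step(blank, df, posterior, services = "hospital")
}

record_severity <- function(df, scheme) {
  num <- den <- numeric(nrow(df))
  for (j in seq_along(scheme)) {
    y <- df[[paste0("y", j)]]
    obs <- !is.na(y)
    num[obs] <- num[obs] + (y[obs] - 1) / (scheme[[j]] - 1)
    den[obs] <- den[obs] + 1
  }
  ifelse(den > 0, num / den, NA_real_)
}

blank_params <- function(n_living, scheme, year_levels) {
  n_cov <- 5L + length(year_levels) - 1L
  zero_cost <- list(use = matrix(0, n_cov, n_living),
                    mean = matrix(c(log(3000), rep(0, n_cov - 1L)),
                                  n_cov, n_living),
                    shape = 1)
  latent_params(
    n_living = n_living, indicators = scheme,
    init = matrix(0, 3L, n_living,
                  dimnames = list(c("intercept", "age_dec", "sex"), NULL)),
    trans = lapply(seq_len(n_living), function(l) {
      B <- matrix(0, 5L, n_living + 1L)
      B[1L, ] <- -2; B[1L, l] <- 0
      rownames(B) <- c("intercept", "sex", "partner", "age_dec", "educ")
      B
    }),
    emission = lapply(scheme, function(K) matrix(0, K, n_living)),
    cost = list(hospital = zero_cost), year_levels = year_levels)
}

#' Fit the latent Markov model by expectation-maximization
#'
#' E-step: scaled forward-backward smoothing over every individual's record
#' sequence, with missing emissions (off-wave indicators, out-of-window
#' costs) contributing nothing. M-step: posterior-weighted multinomial-logit
#' fits for the initial-state and transition models, closed-form
#' posterior-weighted category frequencies for the indicator intercepts, and
#' posterior-weighted two-part (logit + Gamma GLM) fits for the jointly
#' modeled cost services, with a maximum-likelihood dispersion update. Inner
#' fits are run to full convergence each M-step, so the observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' @param panel A `health_panel`.
#' @param n_living Number of living latent states (total states =
#'   `n_living + 1`).
#' @param init Initialization: `"severity"` (k-means partition of records on
#'   mean standardized indicator severity), or `"params"` (start from
#'   `init_params`).
#' @param init_params Starting `latent_params` for `init = "params"`.
#' @param tol Convergence threshold on the relative log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param n_restarts Number of starts (first is deterministic; later ones
#'   jitter the severity partition); the best final log-likelihood is kept.
#' @param seed Seed for restart jitter.
#' @param services Cost services entering the joint likelihood (home care
#'   and LTC are fitted ex post; see [fit_expost_cost_model()]).
#' @param verbose Print one line per iteration.
#' @return A `health_fit`: list with `params`, `loglik`, `trace`,
#'   `iterations`, `converged`, `n_params`, `aic`, `bic`.
#' @export
fit_em <- function(panel, n_living = 3L, init = c("severity", "params"),
                   init_params = NULL, tol = 1e-7, max_iter = 500L,
                   n_restarts = 1L, seed = 1L, services = "hospital",
                   verbose = FALSE) {
  init <- match.arg(init)
  df <- as.data.frame(panel)
  if (!nrow(df)) stop("empty panel")
  scheme <- attr(panel, "indicators")
  sched <- panel_schedule(panel)
  year_levels <- sched$start_year:sched$end_year
  if (!is.null(seed)) set.seed(seed)

  run_one <- function(start_params) {
    params <- start_params
    trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      post <- e_step(params, df)
      ll <- sum(post$loglik)
      trace <- c(trace, ll)
      if (verbose)
        message(sprintf("EM iter %3d  loglik %.6f", iter, ll))
      if (iter > 1L &&
          abs(ll - trace[iter - 1L]) < tol * max(1, abs(ll))) {
        converged <- TRUE
        break
      }
      new_params <- m_step(params, df, post, services = services)
      degenerate <- vapply(seq_len(n_living), function(m)
        sum(post$gamma[, m]), numeric(1L)) < 1
      if (any(degenerate))
        warning("latent state(s) ", paste(which(degenerate), collapse = ","),
                " received near-zero posterior weight; consider fewer ",
                "states or a different start")
      params <- new_params
    }
    list(params = params, loglik = trace[length(trace)], trace = trace,
         iterations = length(trace), converged = converged)
  }

  starts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    starts[[r]] <- if (init == "params" && r == 1L) {
      stopifnot(!is.null(init_params))
      ip <- init_params
      ip$cost <- ip$cost[intersect(names(ip$cost), services)]
      ip
    } else {
      init_from_severity(panel, n_living, year_levels, scheme,
                         jitter = if (r == 1L && init != "params") 0
                         else 0.1)
    }
  }
  fits <- lapply(starts, run_one)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1L), "loglik"))]]

  k <- count_params(best$params, services)
  n_ind <- length(unique(df$id))
  structure(c(best, list(
    n_params = k,
    aic = -2 * best$loglik + 2 * k,
    bic = -2 * best$loglik + k * log(n_ind),
    n_individuals = n_ind, seed = seed
  )), class = "health_fit")
}

count_params <- function(params, services = names(params$cost)) {
  Ml <- params$n_living
  k <- 3L * (Ml - 1L)                       # initial-state logit
  k <- k + Ml * 5L * Ml                     # transition logits
  k <- k + sum((params$indicators - 1L) * Ml)
  for (s in services)
    k <- k + 2L * nrow(params$cost[[s]]$use) * Ml + 1L
  k
}

#' @export
print.health_fit <- function(x, ...) {
  cat("Latent Markov model fit:", x$params$n_living, "living states\n")
  cat(sprintf("  loglik %.3f after %d EM iterations (%s)\n", x$loglik,
              x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  parameters %d  AIC %.1f  BIC %.1f\n", x$n_params, x$aic,
              x$bic))
  invisible(x)
}

#' Compare model fits across numbers of latent states
#'
#' Fits the model for each candidate number of living states and tabulates
#' log-likelihood, parameter count, AIC and BIC, flagging the BIC-minimal
#' specification among converged candidates.
#'
#' @param panel A `health_panel`.
#' @param n_living_candidates Integer vector of living-state counts.
#' @param ... Passed to [fit_em()].
#' @return Data frame with one row per candidate and attribute `"fits"`.
#' @export
select_num_states <- function(panel, n_living_candidates = 2:4, ...) {
  fits <- lapply(n_living_candidates, function(m)
    fit_em(panel, n_living = m, ...))
  tab <- data.frame(
    n_living = n_living_candidates,
    n_states = n_living_candidates + 1L,
    loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
    n_params = vapply(fits, `[[`, numeric(1L), "n_params"),
    aic = vapply(fits, `[[`, numeric(1L), "aic"),
    bic = vapply(fits, `[[`, numeric(1L), "bic"),
    converged = vapply(fits, `[[`, logical(1L), "converged")
  )
  tab$best_bic <- FALSE
  ok <- which(tab$converged)
  if (!length(ok)) {
    warning("no candidate converged; BIC comparison not meaningful")
  } else {
    tab$best_bic[ok[which.min(tab$bic[ok])]] <- TRUE
    if (any(!tab$converged))
      warning("non-converged candidate(s): n_living = ",
              paste(tab$n_living[!tab$converged], collapse = ", "))
  }
  attr(tab, "fits") <- fits
  tab
}

#' Smoothed posterior state probabilities for every individual-year
#'
#' @param fit A `health_fit` (or `latent_params`).
#' @param panel The panel the posteriors are computed on.
#' @return Data frame `id`, `year`, `gamma_1..gamma_M`.
#' @export
posterior_states <- function(fit, panel) {
  params <- if (inherits(fit, "health_fit")) fit$params else fit
  df <- as.data.frame(panel)
  post <- e_step(params, df)
  out <- data.frame(id = df$id, year = df$year)
  for (m in seq_len(params$n_states))
    out[[paste0("gamma_", m)]] <- post$gamma[, m]
  out
}
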