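#' Emission likelihood of one panel record given a latent state
#'
#' Product of the observed-indicator category probabilities and the
#' observed-service two-part cost densities. Missing indicators and
#' unobserved services contribute a factor 1 (the record is transparent to
#' them). A record with `vital_status = "dead"` has likelihood 1 for the
#' death state and 0 for every living state; an alive record has likelihood
#' 0 for the death state.
#'
#' @param params A `latent_params` object.
#' @param record A single panel row (one-row data frame or list) with
#'   covariates, `y1..yJ`, `cost_*` and `vital_status`.
#' @param state State index (living state or death).
#' @return Likelihood value.
#' @export
emission_likelihood <- function(params, record, state) {
  M <- params$n_states
  if (identical(record$vital_status, "dead"))
    return(as.numeric(state == M))
  if (state == M) return(0)
  covs <- list(sex = record$sex, partner = record$partner,
               age = record$age, education = record$education)
  val <- 1
  for (j in seq_along(params$indicators)) {
    y <- record[[paste0("y", j)]]
    if (!is.na(y)) val <- val * indicator_prob(params, state, j, y)
  }
  for (s in names(params$cost)) {
    cost <- record[[paste0("cost_", s)]]
    if (!is.null(cost) && !is.na(cost))
      val <- val * cost_emission_density(params, cost, state, covs, s,
                                         year = record$year)
  }
  val
}

## Emission likelihood matrix for a block of records (n_rec x n_states),
## vectorized over records. Relies on records carrying observed vital
## status: alive records exclude the death state, dead records force it.
emission_matrix <- function(params, df) {
  Ml <- params$n_living
  n <- nrow(df)
  logE <- matrix(0, n, Ml)
  for (j in seq_along(params$indicators)) {
    y <- df[[paste0("y", j)]]
    obs <- which(!is.na(y))
    if (!length(obs)) next
    P <- apply(params$emission[[j]], 2L, function(eta) softmax_vec(eta))
    for (m in seq_len(Ml))
      logE[obs, m] <- logE[obs, m] + log(P[y[obs], m])
  }
  if (length(params$cost)) {
    Xc <- design_cost(df$sex, df$partner, df$age, df$education, df$year,
                      params$year_levels)
    for (s in names(params$cost)) {
      cost <- df[[paste0("cost_", s)]]
      obs <- which(!is.na(cost))
      if (!length(obs)) next
      cm <- params$cost[[s]]
      for (m in seq_len(Ml)) {
        p <- plogis(drop(Xc[obs, , drop = FALSE] %*% cm$use[, m]))
        mu <- exp(drop(Xc[obs, , drop = FALSE] %*% cm$mean[, m]))
        co <- cost[obs]
        ld <- ifelse(co == 0, log1p(-p),
                     log(p) + dgamma(co, shape = cm$shape,
                                     rate = cm$shape / mu, log = TRUE))
        logE[obs, m] <- logE[obs, m] + ld
      }
    }
  }
  E <- cbind(exp(logE), 0)
  dead <- df$vital_status == "dead"
  E[dead, ] <- 0
  E[dead, Ml + 1L] <- 1
  E
}

## Transition array (M x M x n_rec): slice r is the transition matrix from
## record r-1 into record r, built from the origin-year (previous record)
## covariates. Slices for first records are left as identity (unused).
transition_array <- function(params, df, first) {
  M <- params$n_states
  n <- nrow(df)
  A <- array(0, c(M, M, n))
  A[cbind(rep(seq_len(M), n), rep(seq_len(M), n),
          rep(seq_len(n), each = M))] <- 1
  later <- which(!first)
  if (!length(later)) return(A)
  prev <- df[later - 1L, c("sex", "partner", "age", "education")]
  for (l in seq_len(params$n_living)) {
    P <- transition_rows_df(params, l, prev)
    A[l, , later] <- t(P)
  }
  A[M, , later] <- 0
  A[M, M, later] <- 1
  A
}

panel_index <- function(df) {
  stopifnot(nrow(df) > 0)
  ord <- order(df$id, df$year)
  if (!identical(ord, seq_len(nrow(df))))
    stop("records must be sorted by individual and year")
  first <- c(TRUE, df$id[-1L] != df$id[-nrow(df)])
  gaps <- which(!first & df$year != c(0L, df$year[-nrow(df)] + 1L))
  if (length(gaps))
    stop("non-consecutive years for individual ", df$id[gaps[1L]],
         " at year ", df$year[gaps[1L]],
         " (gaps in the annual record are not supported)")
  starts <- which(first)
  lens <- diff(c(starts, nrow(df) + 1L))
  list(first = first, starts = starts, lens = lens,
       ids = df$id[starts])
}

## Full E-step over a panel: one C++ call.
e_step <- function(params, df) {
  idx <- panel_index(df)
  E <- emission_matrix(params, df)
  A <- transition_array(params, df, idx$first)
  firsts <- df[idx$starts, ]
  pi0 <- cbind(t(vapply(seq_along(idx$starts), function(i)
    initial_state_probs(params, firsts$age[i], firsts$sex[i]),
    numeric(params$n_living))), 0)
  out <- fb_all(pi0, E, A, idx$starts, idx$lens)
  out$ids <- idx$ids
  out$index <- idx
  out
}

#' Forward-backward smoothing for one individual
#'
#' Numerically stable (per-step scaled) forward-backward recursions over the
#' individual's consecutive annual records, with missing emissions handled
#' transparently (a year contributes only its observed indicators and
#' costs). Returns the smoothed state probabilities, the pairwise joint
#' transition probabilities, and the exact log-likelihood of the observed
#' record sequence.
#'
#' @param params A `latent_params` object.
#' @param records Data frame of one individual's records, consecutive years.
#' @return List with `gamma` (T x M), `xi` (M x M x T; slice 1 is zero), and
#'   `loglik`.
#' @export
forward_backward <- function(params, records) {
  records <- as.data.frame(records)
  if (length(unique(records$id)) > 1L)
    stop("forward_backward expects records of a single individual")
  out <- e_step(params, records)
  list(gamma = out$gamma, xi = out$xi, loglik = out$loglik[1L])
}

#' Brute-force likelihood by path enumeration
#'
#' Evaluates the marginal likelihood as the literal nested sum over all
#' latent state paths, using only the scalar building blocks
#' ([emission_likelihood()], [transition_row()], [initial_state_probs()]).
#' Serves as an independent oracle for [forward_backward()]; refuses
#' sequences long enough for the enumeration to blow up.
#'
#' @inheritParams forward_backward
#' @return Log-likelihood value.
#' @export
loglik_brute_force <- function(params, records) {
  records <- as.data.frame(records)
  Tn <- nrow(records)
  if (Tn > 8L) stop("path enumeration refused for more than 8 records")
  M <- params$n_states
  pi0 <- c(initial_state_probs(params, records$age[1L], records$sex[1L]), 0)
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), Tn)))
  total <- 0
  for (p in seq_len(nrow(paths))) {
    path <- paths[p, ]
    prob <- pi0[path[1L]] * emission_likelihood(params, records[1L, ],
                                                path[1L])
    t <- 2L
    while (prob > 0 && t <= Tn) {
      covs <- list(sex = records$sex[t - 1L], partner = records$partner[t - 1L],
                   age = records$age[t - 1L],
                   education = records$education[t - 1L])
      prob <- prob * transition_row(params, path[t - 1L], covs)[path[t]] *
        emission_likelihood(params, records[t, ], path[t])
      t <- t + 1L
    }
    total <- total + prob
  }
  log(total)
}
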