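#' Mean standardized severity of each living state
#'
#' For each indicator, the expected category score is mapped linearly so the
#' best possible category is 0 and the worst is 1; the state's severity is
#' the mean over indicators.
#'
#' @param params A `latent_params` object.
#' @return Numeric vector of length `n_living`.
#' @export
state_severity <- function(params) {
  prof <- profile_matrix(params)
  colMeans(prof)
}

profile_matrix <- function(params) {
  Ml <- params$n_living
  out <- matrix(NA_real_, length(params$indicators), Ml,
                dimnames = list(names(params$indicators), NULL))
  for (j in seq_along(params$indicators)) {
    K <- params$indicators[[j]]
    for (m in seq_len(Ml)) {
      p <- indicator_prob(params, m, j)
      out[j, m] <- sum(p * (seq_len(K) - 1)) / (K - 1)
    }
  }
  out
}

#' Permute the living states of a parameter set
#'
#' Applies a consistent relabeling: state `perm[m]` of the input becomes
#' state `m` of the output. Death stays last. The implied probability model
#' is unchanged (multinomial logits are re-referenced after permutation).
#'
#' @param params A `latent_params` object.
#' @param perm Permutation of `1:n_living`.
#' @return The relabeled `latent_params`.
#' @export
permute_states <- function(params, perm) {
  Ml <- params$n_living
  stopifnot(length(perm) == Ml, all(sort(perm) == seq_len(Ml)))
  full <- c(perm, Ml + 1L)
  init <- params$init[, perm, drop = FALSE]
  init <- init - init[, 1L]
  trans <- lapply(seq_len(Ml), function(l) {
    B <- params$trans[[perm[l]]][, full, drop = FALSE]
    B <- B - B[, l]
    dimnames(B) <- dimnames(params$trans[[perm[l]]])
    B
  })
  emission <- lapply(params$emission, function(E) {
    E <- E[, perm, drop = FALSE]
    sweep(E, 2L, E[1L, ], "-")
  })
  cost <- lapply(params$cost, function(cm)
    list(use = cm$use[, perm, drop = FALSE],
         mean = cm$mean[, perm, drop = FALSE], shape = cm$shape))
  latent_params(n_living = Ml, indicators = params$indicators, init = init,
                trans = trans, emission = emission, cost = cost,
                year_levels = params$year_levels)
}

#' Order latent states from good to poor health
#'
#' Permutes the living states so mean standardized indicator severity is
#' increasing (state 1 = good, last living state = poor); death stays last.
#' Ties are broken by the state-specific death probability at the reference
#' profile (men aged 75, with partner, middle education). Identification of
#' the mixture is by this ordering, not by constraints during estimation.
#'
#' @param fit A `health_fit` or `latent_params`.
#' @return Object of the same class with states relabeled.
#' @export
label_states <- function(fit) {
  params <- if (inherits(fit, "health_fit")) fit$params else fit
  sev <- state_severity(params)
  ref <- list(sex = 0, partner = 1, age = 75, education = 2)
  death_p <- vapply(seq_len(params$n_living), function(l)
    transition_row(params, l, ref)[params$n_states], numeric(1L))
  perm <- order(sev, death_p)
  out <- permute_states(params, perm)
  if (inherits(fit, "health_fit")) {
    fit$params <- out
    fit
  } else out
}

#' Standardized expected indicator outcome per state
#'
#' Per indicator and living state, the expected category mapped linearly to
#' 0 (best possible outcome) to 1 (worst possible outcome).
#'
#' @param fit A labeled `health_fit` or `latent_params`.
#' @return Data frame: indicator, one column per living state.
#' @export
standardized_state_profiles <- function(fit) {
  params <- if (inherits(fit, "health_fit")) fit$params else fit
  prof <- profile_matrix(params)
  out <- data.frame(indicator = rownames(prof))
  for (m in seq_len(ncol(prof)))
    out[[paste0("state_", m)]] <- prof[, m]
  out
}

#' Expected annual cost by age for one state and service
#'
#' `p_use(x) * mean(x)` along an age range, other covariates at baseline
#' levels (with partner, middle education, reference calendar year).
#'
#' @param fit A labeled `health_fit` or `latent_params`.
#' @param state Living-state index.
#' @param sex 0 = male, 1 = female.
#' @param service Service name with a fitted cost model.
#' @param ages Integer vector of ages.
#' @return Data frame `age`, `expected_cost`.
#' @export
expected_cost_curve <- function(fit, state, sex, service, ages = 65:95) {
  params <- if (inherits(fit, "health_fit")) fit$params else fit
  cost_model(params, service)
  vals <- vapply(ages, function(a)
    expected_annual_cost(params, state,
                         list(sex = sex, partner = 1, age = a,
                              education = 2), service),
    numeric(1L))
  data.frame(age = ages, expected_cost = vals)
}
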