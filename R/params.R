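#' @useDynLib healthmarkov, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dgamma glm.fit kmeans plogis rbinom rgamma rmultinom
#'   rnorm runif binomial Gamma uniroot setNames aggregate quantile sd
#' @importFrom utils read.csv write.csv modifyList
NULL

# Service types with fitted cost models. Hospital costs enter the joint
# likelihood; home care and institutional LTC are fitted ex post on their
# registry window.
SERVICES <- c("hospital", "homecare", "ltc")

#' Default indicator scheme
#'
#' Seven categorical health and disability indicators: self-perceived health
#' (5 categories), mobility limitation score (4), categorized dressing
#' performance test (3), Global Activity Limitation Indicator (3), chronic
#' disease count 0/1/2+ (3), depressive symptoms above/below the CES-D
#' screening cut-off (2), cognitive impairment by MMSE cut-off (2). Category
#' 1 is always the best outcome and category K the worst.
#'
#' @return Named integer vector of category counts per indicator.
#' @export
indicator_scheme <- function() {
  c(sph = 5L, mobility = 4L, performance = 3L, gali = 3L,
    chronic = 3L, depression = 2L, cognition = 2L)
}

## Covariate design builders. Age is centered at 75 and scaled per decade;
## education is an ordinal score 1..3 centered at 2. Calendar year enters the
## cost models as dummies relative to the first panel year; years outside
## `year_levels` (e.g. projection years) fall back to the reference level.

design_init <- function(age, sex) {
  cbind(intercept = 1, age_dec = (age - 75) / 10, sex = sex)
}

design_trans <- function(sex, partner, age, education) {
  cbind(intercept = 1, sex = sex, partner = partner,
        age_dec = (age - 75) / 10, educ = education - 2)
}

design_cost <- function(sex, partner, age, education, year, year_levels) {
  base <- cbind(intercept = 1, sex = sex, partner = partner,
                age_dec = (age - 75) / 10, educ = education - 2)
  if (length(year_levels) > 1L) {
    dummies <- vapply(year_levels[-1L],
                      function(y) as.numeric(year == y),
                      numeric(length(year)))
    if (length(year) == 1L) dummies <- matrix(dummies, nrow = 1L)
    colnames(dummies) <- paste0("year", year_levels[-1L])
    base <- cbind(base, dummies)
  }
  base
}

softmax_rows <- function(eta) {
  m <- eta[cbind(seq_len(nrow(eta)), max.col(eta, ties.method = "first"))]
  e <- exp(eta - m)
  e / rowSums(e)
}

softmax_vec <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Construct a latent Markov parameter set
#'
#' Container for all parameters of the latent Markov health model: the
#' initial-state multinomial logit (covariates age and sex at first
#' observation), one multinomial transition logit per living origin state
#' (covariates sex, partner status, age, education; destinations include
#' death), per-indicator multinomial intercepts per living state (no
#' covariates), and per-service two-part cost models per living state
#' (use-probability logit and Gamma log-link mean, sharing one dispersion
#' parameter per service). Death is the last state and is absorbing.
#'
#' @param n_living Number of living latent states (death is added as state
#'   `n_living + 1`).
#' @param indicators Named integer vector of category counts, as
#'   [indicator_scheme()].
#' @param init Coefficient matrix for the initial-state logit,
#'   3 x `n_living` (rows intercept, age per decade centered at 75, sex);
#'   column 1 is the reference and must be zero.
#' @param trans List of `n_living` coefficient matrices, each
#'   5 x `n_living + 1` (rows intercept, sex, partner, age per decade,
#'   education score); the origin's own column is the reference (zero).
#' @param emission List of logit matrices, one per indicator, each
#'   K x `n_living` with the first row (best category) as reference.
#' @param cost Named list per service: `use` and `mean` coefficient matrices
#'   (p x `n_living`) plus scalar `shape`. May omit services (fitted later).
#' @param year_levels Integer vector of panel calendar years; the first is
#'   the reference level of the cost models' calendar-year dummies.
#'
#' @return An object of class `latent_params`.
#' @export
latent_params <- function(n_living, indicators, init, trans, emission,
                          cost = list(), year_levels = 1995:2007) {
  stopifnot(n_living >= 1L, all(indicators >= 2L))
  obj <- structure(list(
    n_living = as.integer(n_living),
    n_states = as.integer(n_living) + 1L,
    indicators = indicators,
    init = init, trans = trans, emission = emission,
    cost = cost, year_levels = as.integer(year_levels)
  ), class = "latent_params")
  validate_params(obj)
  obj
}

validate_params <- function(p) {
  stopifnot(inherits(p, "latent_params"))
  M <- p$n_living
  if (!all(dim(p$init) == c(3L, M)))
    stop("init must be 3 x n_living")
  if (any(p$init[, 1L] != 0))
    stop("initial-state reference column (state 1) must be zero")
  if (length(p$trans) != M) stop("one transition logit per living origin")
  n_cost_cov <- 5L + max(0L, length(p$year_levels) - 1L)
  for (l in seq_len(M)) {
    B <- p$trans[[l]]
    if (!all(dim(B) == c(5L, M + 1L)))
      stop("transition coefficient matrix must be 5 x n_states")
    if (any(B[, l] != 0))
      stop("own-state reference column must be zero (origin ", l, ")")
  }
  if (length(p$emission) != length(p$indicators))
    stop("one emission logit matrix per indicator")
  for (j in seq_along(p$emission)) {
    E <- p$emission[[j]]
    if (nrow(E) != p$indicators[[j]] || ncol(E) != M)
      stop("emission matrix ", j, " must be K x n_living")
    if (any(E[1L, ] != 0))
      stop("best category is the reference (zero logit), indicator ", j)
  }
  for (s in names(p$cost)) {
    cm <- p$cost[[s]]
    stopifnot(is.matrix(cm$use), is.matrix(cm$mean))
    if (ncol(cm$use) != M || ncol(cm$mean) != M)
      stop("cost model for ", s, " needs one column per living state")
    if (nrow(cm$use) != n_cost_cov || nrow(cm$mean) != n_cost_cov)
      stop("cost model for ", s, " needs ", n_cost_cov, " coefficient rows")
    if (!is.numeric(cm$shape) || cm$shape <= 0)
      stop("Gamma shape for ", s, " must be positive")
  }
  invisible(p)
}

#' Initial-state probabilities over living states
#'
#' @param params A `latent_params` object.
#' @param age,sex Covariates at first observation (sex coded 0 = male,
#'   1 = female).
#' @return Probability vector of length `n_living` (death has probability 0
#'   at entry).
#' @export
initial_state_probs <- function(params, age, sex) {
  eta <- drop(design_init(age, sex) %*% params$init)
  softmax_vec(eta)
}

#' Category probabilities of a health indicator given the latent state
#'
#' Softmax of the indicator's state-specific multinomial intercepts. The
#' death state emits no indicators and cannot be queried.
#'
#' @param params A `latent_params` object.
#' @param state Living-state index.
#' @param indicator Indicator index (or name).
#' @param category Optional category index; if `NULL` the full probability
#'   vector is returned.
#' @return Probability or probability vector.
#' @export
indicator_prob <- function(params, state, indicator, category = NULL) {
  if (state > params$n_living)
    stop("the death state has no indicator emissions")
  p <- softmax_vec(params$emission[[indicator]][, state])
  if (is.null(category)) p else p[[category]]
}

#' Transition probability row for one origin state
#'
#' @param params A `latent_params` object.
#' @param origin Origin state index (living state or death).
#' @param covariates List with `sex`, `partner`, `age`, `education`.
#' @return Probability vector over all `n_states` destinations. The death
#'   origin returns the absorbing unit vector.
#' @export
transition_row <- function(params, origin, covariates) {
  M <- params$n_states
  if (origin == M) {
    out <- numeric(M); out[M] <- 1
    return(out)
  }
  x <- design_trans(covariates$sex, covariates$partner,
                    covariates$age, covariates$education)
  softmax_vec(drop(x %*% params$trans[[origin]]))
}

## Vectorized transition probabilities: one row per record for a fixed
## origin. df must carry sex, partner, age, education columns.
transition_rows_df <- function(params, origin, df) {
  X <- design_trans(df$sex, df$partner, df$age, df$education)
  softmax_rows(X %*% params$trans[[origin]])
}

#' Probability of any use of a service given state and covariates
#' @inheritParams transition_row
#' @param state Living-state index.
#' @param service One of `"hospital"`, `"homecare"`, `"ltc"`.
#' @param year Calendar year (maps to the cost model's year dummies; years
#'   outside the panel fall back to the reference level).
#' @return Use probability in (0, 1).
#' @export
cost_use_prob <- function(params, state, covariates, service,
                          year = params$year_levels[1L]) {
  cm <- cost_model(params, service)
  x <- design_cost(covariates$sex, covariates$partner, covariates$age,
                   covariates$education, year, params$year_levels)
  plogis(drop(x %*% cm$use[, state]))
}

#' Conditional mean of positive costs (Gamma GLM, log link)
#' @inheritParams cost_use_prob
#' @return Mean positive annual cost.
#' @export
cost_mean <- function(params, state, covariates, service,
                      year = params$year_levels[1L]) {
  cm <- cost_model(params, service)
  x <- design_cost(covariates$sex, covariates$partner, covariates$age,
                   covariates$education, year, params$year_levels)
  exp(drop(x %*% cm$mean[, state]))
}

cost_model <- function(params, service) {
  cm <- params$cost[[service]]
  if (is.null(cm)) stop("no fitted cost model for service '", service, "'")
  cm
}

#' Two-part cost emission density
#'
#' Density of annual cost under the two-part model: mass `1 - p_use` at
#' exactly zero, and `p_use` times a Gamma density (log-link mean, per-service
#' dispersion) on the positive part.
#'
#' @inheritParams cost_use_prob
#' @param cost Non-negative cost amount.
#' @param log Return the log density?
#' @return Density (or log density) value.
#' @export
cost_emission_density <- function(params, cost, state, covariates, service,
                                  year = params$year_levels[1L], log = FALSE) {
  if (any(cost < 0)) stop("costs must be non-negative")
  p <- cost_use_prob(params, state, covariates, service, year)
  mu <- cost_mean(params, state, covariates, service, year)
  shape <- cost_model(params, service)$shape
  ld <- ifelse(cost == 0, log(1 - p),
               log(p) + dgamma(cost, shape = shape, rate = shape / mu,
                               log = TRUE))
  if (log) ld else exp(ld)
}

#' Expected annual cost given state and covariates
#'
#' `p_use * mean`, the unconditional expectation of the two-part model.
#'
#' @inheritParams cost_use_prob
#' @return Expected annual cost.
#' @export
expected_annual_cost <- function(params, state, covariates, service,
                                 year = params$year_levels[1L]) {
  cost_use_prob(params, state, covariates, service, year) *
    cost_mean(params, state, covariates, service, year)
}

#' Write / read a parameter set as JSON
#'
#' The JSON document carries a schema version, all coefficient matrices and
#' the covariate conventions, and round-trips losslessly.
#'
#' @param params A `latent_params` object.
#' @param path File path.
#' @return `read_params` returns a `latent_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  doc <- list(
    schema = "healthmarkov-params-1",
    n_living = params$n_living,
    indicators = as.list(params$indicators),
    init = params$init,
    trans = params$trans,
    emission = params$emission,
    cost = lapply(params$cost, function(cm)
      list(use = cm$use, mean = cm$mean, shape = cm$shape)),
    year_levels = params$year_levels
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "healthmarkov-params-1"))
    stop("unrecognized parameter file schema")
  ## jsonlite collapses lists of same-shaped matrices into a 3-d array
  as_matrix_list <- function(x) {
    if (is.array(x) && length(dim(x)) == 3L)
      lapply(seq_len(dim(x)[1L]), function(i) x[i, , ]) else
        lapply(x, identity)
  }
  latent_params(
    n_living = doc$n_living,
    indicators = unlist(doc$indicators),
    init = doc$init,
    trans = as_matrix_list(doc$trans),
    emission = as_matrix_list(doc$emission),
    cost = lapply(doc$cost, function(cm)
      list(use = cm$use, mean = cm$mean, shape = cm$shape)),
    year_levels = doc$year_levels
  )
}

#' @export
print.latent_params <- function(x, ...) {
  cat("Latent Markov health model parameters\n")
  cat("  living states:", x$n_living, "(+ absorbing death state)\n")
  cat("  indicators:", paste0(names(x$indicators), "(", x$indicators, ")",
                              collapse = " "), "\n")
  cat("  cost models:", if (length(x$cost)) paste(names(x$cost),
                                                  collapse = ", ")
      else "none", "\n")
  cat("  panel years:", x$year_levels[1L], "-",
      x$year_levels[length(x$year_levels)], "\n")
  invisible(x)
}
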