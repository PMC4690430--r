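#' Morbidity scenario specifications
#'
#' Nine scenarios: a baseline (2010 rates and initial profile frozen) and
#' eight sub-scenarios of three hypotheses about how a given 2050 life
#' expectancy at 65 is reached. Expansion of morbidity (`1o`, `1++`) lowers
#' the probability of dying from every living state by the same annual
#' proportion. Compression of morbidity (`2o`, `2+`, `2++`) raises the
#' probabilities of remaining in good or moderate health relative to worse
#' outcomes. Dynamic equilibrium (`3o`, `3+`, `3++`) shifts transitions from
#' good/moderate toward moderate health while a second rate on poor-state
#' mortality holds expected poor-state years at their baseline value.
#' `+` variants additionally ramp the initial health profile of new
#' 65-year-olds (good share to 100% in 2050 for compression; moderate share
#' to 45% for dynamic equilibrium); `++` variants use the optimistic life
#' expectancy targets.
#'
#' Standard 2050 targets for remaining LE at 65 are 21.1 (men) / 24.6
#' (women); optimistic targets are 24.1 / 27.6.
#'
#' @param id One of `"baseline"`, `"1o"`, `"1++"`, `"2o"`, `"2+"`, `"2++"`,
#'   `"3o"`, `"3+"`, `"3++"`.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(id) {
  std <- c(male = 21.1, female = 24.6)
  opt <- c(male = 24.1, female = 27.6)
  tab <- list(
    "baseline" = list(hypothesis = "baseline",   ramp = FALSE, target = NULL),
    "1o"   = list(hypothesis = "expansion",   ramp = FALSE, target = std),
    "1++"  = list(hypothesis = "expansion",   ramp = FALSE, target = opt),
    "2o"   = list(hypothesis = "compression", ramp = FALSE, target = std),
    "2+"   = list(hypothesis = "compression", ramp = TRUE,  target = std),
    "2++"  = list(hypothesis = "compression", ramp = TRUE,  target = opt),
    "3o"   = list(hypothesis = "dynamic",     ramp = FALSE, target = std),
    "3+"   = list(hypothesis = "dynamic",     ramp = TRUE,  target = std),
    "3++"  = list(hypothesis = "dynamic",     ramp = TRUE,  target = opt)
  )
  if (!id %in% names(tab)) stop("unknown scenario id: ", id)
  e <- tab[[id]]
  ramp <- if (!e$ramp) NULL else if (e$hypothesis == "compression")
    list(state = 1L, endpoint = 1.0) else list(state = 2L, endpoint = 0.45)
  structure(list(id = id, hypothesis = e$hypothesis,
                 uses_initial_ramp = e$ramp, ramp = ramp,
                 le_target = e$target, rates = list()),
            class = "scenario_spec")
}

#' All nine scenario specifications
#' @return Named list of `scenario_spec` objects.
#' @export
scenario_set <- function() {
  ids <- c("baseline", "1o", "1++", "2o", "2+", "2++", "3o", "3+", "3++")
  setNames(lapply(ids, scenario_spec), ids)
}

#' Compounded annual adjustment multiplier
#'
#' `(1 - x)^(year - base_year)`: the cumulative effect in `year` of a
#' proportional adjustment of `x` per year since the base year.
#'
#' @param x Annual rate in `[0, 1)`.
#' @param year Calendar year (`>= base_year`).
#' @param base_year Base calendar year.
#' @return Multiplier in `(0, 1]`.
#' @export
compound_factor <- function(x, year, base_year = 2010) {
  stopifnot(x >= 0, x < 1, all(year >= base_year))
  (1 - x)^(year - base_year)
}

check_row <- function(row) {
  if (any(row < -1e-12) || abs(sum(row) - 1) > 1e-9)
    stop("transition row must be a probability vector (non-negative, ",
         "summing to 1)")
  invisible(row)
}

#' Scenario adjustment operators on a transition probability row
#'
#' Each operator rescales selected entries of a row-stochastic transition
#' row by a compounded multiplier and reallocates the freed probability
#' mass, leaving the row stochastic. `apply_expansion` scales the death
#' entry and adds the freed mass to the origin's own-state entry (survivors
#' remain in their current health state). `apply_compression` scales, for
#' good/moderate origins, all transitions to strictly worse living states
#' and to death, adding the freed mass to the own-state entry; the
#' poor-origin row is returned unchanged. `apply_dynamic` scales, for
#' good/moderate origins, the transitions to poor health and death and adds
#' the freed mass to the moderate entry; for the poor origin it scales the
#' death entry by its own multiplier, freed mass to the poor diagonal.
#'
#' @param row Probability row over `n_living + 1` states (death last).
#' @param origin Origin state index (living).
#' @param multiplier Compounded multiplier in `(0, 1]` (see
#'   [compound_factor()]).
#' @return Adjusted probability row.
#' @export
apply_expansion <- function(row, origin, multiplier) {
  check_row(row)
  M <- length(row)
  freed <- row[M] * (1 - multiplier)
  row[M] <- row[M] * multiplier
  row[origin] <- row[origin] + freed
  row
}

#' @rdname apply_expansion
#' @export
apply_compression <- function(row, origin, multiplier) {
  check_row(row)
  M <- length(row)
  poor <- M - 1L
  if (origin >= poor) return(row)
  worse <- c(seq.int(origin + 1L, poor), M)
  freed <- sum(row[worse]) * (1 - multiplier)
  row[worse] <- row[worse] * multiplier
  row[origin] <- row[origin] + freed
  row
}

#' @rdname apply_expansion
#' @param multiplier_main Compounded multiplier on good/moderate-origin
#'   transitions to poor health and death.
#' @param multiplier_poor_death Compounded multiplier on the poor-origin
#'   death probability.
#' @export
apply_dynamic <- function(row, origin, multiplier_main,
                          multiplier_poor_death) {
  check_row(row)
  M <- length(row)
  poor <- M - 1L
  if (origin < poor) {
    sel <- c(poor, M)
    freed <- sum(row[sel]) * (1 - multiplier_main)
    row[sel] <- row[sel] * multiplier_main
    row[2L] <- row[2L] + freed
  } else {
    freed <- row[M] * (1 - multiplier_poor_death)
    row[M] <- row[M] * multiplier_poor_death
    row[poor] <- row[poor] + freed
  }
  row
}

#' Scenario-adjusted transition model
#'
#' Couples a fitted (labeled) parameter set with a scenario specification
#' and base year. At calendar year 2010 every scenario reproduces the
#' unadjusted model exactly.
#'
#' @param params A labeled `latent_params` (or `health_fit`).
#' @param spec A `scenario_spec` (calibrated for non-baseline scenarios
#'   before life tables or projections are computed).
#' @param base_year Base calendar year of the scenario machinery.
#' @return A `scenario_model` list.
#' @export
scenario_model <- function(params, spec, base_year = 2010) {
  if (inherits(params, "health_fit")) params <- params$params
  structure(list(params = params, spec = spec, base_year = base_year),
            class = "scenario_model")
}

scenario_rates <- function(spec, sex) {
  sx <- if (sex == 0) "male" else "female"
  r <- spec$rates[[sx]]
  if (is.null(r))
    stop("scenario '", spec$id, "' has no calibrated rate for ", sx,
         "; run calibrate() first")
  r
}

#' Transition row under a scenario in a given calendar year
#'
#' The baseline row from the fitted transition model, with the scenario's
#' operator applied at the compounded adjustment multiplier for that year.
#'
#' @param model A `scenario_model`.
#' @param origin Origin state (living or death).
#' @param covariates List with `sex`, `partner`, `age`, `education`.
#' @param year Calendar year (>= base year).
#' @return Probability row over all states.
#' @export
scenario_transition_row <- function(model, origin, covariates, year) {
  row <- transition_row(model$params, origin, covariates)
  adjust_row(model, row, origin, covariates$sex, year)
}

adjust_row <- function(model, row, origin, sex, year) {
  spec <- model$spec
  if (spec$hypothesis == "baseline" || origin == length(row)) return(row)
  if (year <= model$base_year) return(row)
  r <- scenario_rates(spec, sex)
  m_main <- compound_factor(r$x, year, model$base_year)
  switch(spec$hypothesis,
         expansion = apply_expansion(row, origin, m_main),
         compression = apply_compression(row, origin, m_main),
         dynamic = apply_dynamic(row, origin, m_main,
                                 compound_factor(r$x_poor_death, year,
                                                 model$base_year)))
}

#' Initial health profile of new 65-year-olds under a scenario
#'
#' Scenarios with an initial-profile ramp interpolate the targeted state
#' share linearly between its 2010 value and the 2050 endpoint (good health
#' to 100% for compression; moderate health to 45% for dynamic
#' equilibrium), allocating the remaining mass proportionally over the
#' other living states. Scenarios without ramps return the 2010 profile
#' unchanged.
#'
#' @param spec A `scenario_spec`.
#' @param year Calendar year in `[2010, 2050]`.
#' @param baseline_profile Living-state shares at 65 in 2010 (sums to 1).
#' @return Probability vector over living states.
#' @export
initial_profile <- function(spec, year, baseline_profile) {
  if (abs(sum(baseline_profile) - 1) > 1e-9)
    stop("baseline profile must sum to 1 over living states")
  stopifnot(year >= 2010, year <= 2050)
  if (!isTRUE(spec$uses_initial_ramp)) return(baseline_profile)
  s <- spec$ramp$state
  frac <- (year - 2010) / 40
  target <- baseline_profile[s] +
    frac * (spec$ramp$endpoint - baseline_profile[s])
  out <- baseline_profile
  rest <- sum(baseline_profile[-s])
  out[-s] <- if (rest > 0)
    baseline_profile[-s] * (1 - target) / rest else (1 - target) /
    (length(out) - 1L)
  out[s] <- target
  out
}

#' Baseline living-state shares at a given entry age
#'
#' @param params A `latent_params`.
#' @param sex 0 = male, 1 = female.
#' @param age Entry age.
#' @return Probability vector over living states.
#' @export
baseline_profile_at <- function(params, sex, age = 65) {
  initial_state_probs(params, age, sex)
}
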