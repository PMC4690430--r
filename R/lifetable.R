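#' Remaining life expectancy at an entry age, decomposed by health state
#'
#' Propagates the entry-age health profile through successive annual
#' scenario-adjusted transition rows, accumulating expected years per
#' living state. Under the default period convention the scenario
#' adjustment is frozen at its value for the stated calendar year while
#' ages advance; under the cohort convention the calendar year advances
#' with age. A half-year correction (configurable) credits the year of
#' death with half a person-year, attributed to the state occupied at the
#' start of that year; ages are capped at `age_cap`.
#'
#' @param model A `scenario_model` (baseline or calibrated).
#' @param sex 0 = male, 1 = female.
#' @param year Calendar year the life table refers to.
#' @param entry_age Entry age (default 65).
#' @param convention `"period"` (rates frozen at `year`) or `"cohort"`
#'   (calendar advances as the cohort ages).
#' @param age_cap Terminal age; survivors beyond it are not counted.
#' @param half_year Apply the half-year death correction.
#' @param partner,education Representative covariate levels used along the
#'   age profile.
#' @param profile Optional entry profile over living states; defaults to
#'   the scenario's (possibly ramped) initial profile at `year`.
#' @return List of class `life_table_result`: `total`, `by_state`, and the
#'   call's conventions.
#' @export
remaining_life_expectancy <- function(model, sex, year = 2050,
                                      entry_age = 65,
                                      convention = c("period", "cohort"),
                                      age_cap = 110, half_year = TRUE,
                                      partner = 1, education = 2,
                                      profile = NULL) {
  convention <- match.arg(convention)
  params <- model$params
  Ml <- params$n_living
  M <- params$n_states
  if (is.null(profile))
    profile <- initial_profile(model$spec, min(year, 2050),
                               baseline_profile_at(params, sex, entry_age))
  v <- profile
  years <- numeric(Ml)
  for (a in seq.int(entry_age, age_cap - 1L)) {
    cal <- if (convention == "period") year else year + (a - entry_age)
    covs <- list(sex = sex, partner = partner, age = a,
                 education = education)
    P <- t(vapply(seq_len(Ml), function(l)
      scenario_transition_row(model, l, covs, cal), numeric(M)))
    d <- P[, M]
    years <- years + v - if (half_year) 0.5 * v * d else 0
    v <- drop(v %*% P[, seq_len(Ml), drop = FALSE])
    if (sum(v) < 1e-14) break
  }
  structure(list(total = sum(years), by_state = years, sex = sex,
                 year = year, entry_age = entry_age,
                 convention = convention, age_cap = age_cap,
                 half_year = half_year, scenario = model$spec$id),
            class = "life_table_result")
}

#' @export
print.life_table_result <- function(x, ...) {
  cat(sprintf(
    "Remaining LE at %d (%s, %d, scenario %s): %.3f years\n",
    x$entry_age, if (x$sex == 0) "men" else "women", x$year, x$scenario,
    x$total))
  cat("  by state:", paste(sprintf("%.3f", x$by_state), collapse = " / "),
      "\n")
  invisible(x)
}

le_at <- function(params, spec, sex, year = 2050, ...) {
  remaining_life_expectancy(scenario_model(params, spec), sex, year, ...)
}

bisect <- function(f, lower, upper, f_lower = NULL, f_upper = NULL,
                   tol_x = 1e-6, max_iter = 200L) {
  fl <- if (is.null(f_lower)) f(lower) else f_lower
  fu <- if (is.null(f_upper)) f(upper) else f_upper
  if (fl > 0 || fu < 0)
    return(list(root = NA_real_, f_lower = fl, f_upper = fu,
                iterations = 0L))
  iter <- 0L
  log <- list()
  while (upper - lower > tol_x && iter < max_iter) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    iter <- iter + 1L
    log[[iter]] <- c(x = mid, f = fm)
    if (fm < 0) lower <- mid else upper <- mid
  }
  list(root = (lower + upper) / 2, iterations = iter,
       trace = do.call(rbind, log), f_lower = fl, f_upper = fu)
}

#' Calibrate a scenario's annual adjustment rate(s) to a life expectancy
#' target
#'
#' Solves numerically for the annual proportional adjustment rate `x` such
#' that remaining life expectancy at 65 in 2050 under the scenario equals
#' the scenario's target for the given sex (bracketing plus bisection; the
#' iteration log is retained). For dynamic-equilibrium scenarios a nested
#' two-dimensional solve is used: for each candidate `x`, an inner
#' bisection finds the poor-state mortality rate `x_poor_death` that holds
#' expected poor-state years at their baseline value, and the outer
#' bisection moves `x` until the life expectancy target is met. For
#' scenarios with an initial-profile ramp the ramp is fixed first and the
#' transition adjustment is solved conditional on it.
#'
#' @param params A labeled `latent_params` (or `health_fit`).
#' @param spec A `scenario_spec` with targets.
#' @param sex 0 = male, 1 = female (calibration is per sex).
#' @param target Optional override of the scenario's LE target.
#' @param tol_le Acceptable absolute LE deviation (years).
#' @param tol_x Bisection tolerance on the rate.
#' @param x_max Upper bracket for annual rates.
#' @param ... Life-table conventions passed on (`age_cap`, `half_year`, ...).
#' @return The `scenario_spec` with `rates[[sex]]` set (`x`, and
#'   `x_poor_death` for dynamic scenarios) plus achieved values and the
#'   iteration log.
#' @export
calibrate <- function(params, spec, sex, target = NULL, tol_le = 0.005,
                      tol_x = 1e-6, x_max = 0.5, ...) {
  if (inherits(params, "health_fit")) params <- params$params
  if (spec$hypothesis == "baseline")
    stop("the baseline scenario has no adjustment rate to calibrate")
  sx <- if (sex == 0) "male" else "female"
  if (is.null(target)) target <- spec$le_target[[sx]]
  with_rates <- function(x, x_pd = NULL) {
    s <- spec
    s$rates[[sx]] <- list(x = x, x_poor_death = x_pd)
    s
  }
  baseline <- le_at(params, scenario_spec("baseline"), sex, ...)

  if (spec$hypothesis %in% c("expansion", "compression")) {
    f <- function(x) le_at(params, with_rates(x), sex, ...)$total - target
    sol <- bisect(f, 0, x_max, tol_x = tol_x)
    if (is.na(sol$root))
      stop(sprintf(
        "LE target %.2f unreachable for scenario %s (%s): achievable range %.3f to %.3f",
        target, spec$id, sx, sol$f_lower + target, sol$f_upper + target))
    out <- with_rates(sol$root)
  } else {
    poor_target <- baseline$by_state[params$n_living]
    ## inner solve: hold expected poor-state years at baseline; when that is
    ## impossible at a candidate x (bisection endpoints can overshoot the
    ## feasible region), clamp to the bracket boundary so the outer solve
    ## stays defined, and verify feasibility at the solution afterwards
    inner <- function(x) {
      g <- function(x_pd)
        le_at(params, with_rates(x, x_pd), sex,
              ...)$by_state[params$n_living] - poor_target
      s <- bisect(g, 0, 0.99, tol_x = tol_x)
      if (!is.na(s$root)) return(s$root)
      if (s$f_lower > 0) 0 else 0.99
    }
    f <- function(x) le_at(params, with_rates(x, inner(x)), sex,
                           ...)$total - target
    sol <- bisect(f, 0, x_max, tol_x = tol_x)
    if (is.na(sol$root))
      stop(sprintf(
        "LE target %.2f unreachable for scenario %s (%s): achievable range %.3f to %.3f",
        target, spec$id, sx, sol$f_lower + target, sol$f_upper + target))
    out <- with_rates(sol$root, inner(sol$root))
    achieved_poor <- le_at(params, out, sex,
                           ...)$by_state[params$n_living]
    if (abs(achieved_poor - poor_target) > tol_le)
      stop(sprintf(
        "dynamic-equilibrium constraint unreachable for scenario %s (%s): poor-state years %.3f vs baseline %.3f at the LE solution",
        spec$id, sx, achieved_poor, poor_target))
  }
  achieved <- le_at(params, out, sex, ...)
  if (abs(achieved$total - target) > tol_le)
    warning(sprintf(
      "calibration for %s (%s) achieved LE %.4f vs target %.4f",
      spec$id, sx, achieved$total, target))
  out$rates[[sx]]$achieved_le <- achieved$total
  out$rates[[sx]]$achieved_poor_years <-
    achieved$by_state[params$n_living]
  out$rates[[sx]]$target <- target
  out$rates[[sx]]$iterations <- sol$iterations
  out$rates[[sx]]$trace <- sol$trace
  out
}

#' Calibrate every non-baseline scenario for both sexes
#'
#' @param params A labeled `latent_params` (or `health_fit`).
#' @param specs Named list of `scenario_spec` (default [scenario_set()]).
#' @param ... Passed to [calibrate()].
#' @return The list of specs with calibrated rates.
#' @export
calibrate_all <- function(params, specs = scenario_set(), ...) {
  for (id in names(specs)) {
    if (specs[[id]]$hypothesis == "baseline") next
    for (sex in c(0, 1))
      specs[[id]] <- calibrate(params, specs[[id]], sex, ...)
  }
  specs
}
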