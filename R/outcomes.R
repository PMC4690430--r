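#' Expected remaining-lifetime costs at an entry age, by state and service
#'
#' Propagates the entry profile through the scenario-adjusted transition
#' model exactly as [remaining_life_expectancy()] does, and accumulates per
#' projected year the expected annual cost of each service weighted by
#' state occupancy. Costs accrue to the state occupied at the start of the
#' year; the year of death carries the same half-year weight as the life
#' table. Amounts are undiscounted, at the cost models' reference calendar
#' level.
#'
#' @inheritParams remaining_life_expectancy
#' @param services Services to accumulate (all fitted by default).
#' @return A `lifetime_cost_result`: data frame `service`, `state`,
#'   `expected_cost`, with the life-table occupancies as attributes.
#' @export
lifetime_costs <- function(model, sex, year = 2050, entry_age = 65,
                           convention = c("period", "cohort"),
                           services = names(model$params$cost),
                           age_cap = 110, half_year = TRUE, partner = 1,
                           education = 2, profile = NULL) {
  convention <- match.arg(convention)
  params <- model$params
  if (!length(services)) stop("no fitted cost models")
  for (s in services) cost_model(params, s)
  Ml <- params$n_living
  M <- params$n_states
  if (is.null(profile))
    profile <- initial_profile(model$spec, min(year, 2050),
                               baseline_profile_at(params, sex, entry_age))
  v <- profile
  acc <- matrix(0, length(services), Ml,
                dimnames = list(services, seq_len(Ml)))
  years <- numeric(Ml)
  for (a in seq.int(entry_age, age_cap - 1L)) {
    cal <- if (convention == "period") year else
      year + (a - entry_age) + 1L
    covs <- list(sex = sex, partner = partner, age = a,
                 education = education)
    P <- t(vapply(seq_len(Ml), function(l)
      scenario_transition_row(model, l, covs, cal), numeric(M)))
    d <- P[, M]
    w <- v - if (half_year) 0.5 * v * d else 0
    years <- years + w
    for (s in services) {
      ec <- vapply(seq_len(Ml), function(m)
        expected_annual_cost(params, m, covs, s), numeric(1L))
      acc[s, ] <- acc[s, ] + w * ec
    }
    v <- drop(v %*% P[, seq_len(Ml), drop = FALSE])
    if (sum(v) < 1e-14) break
  }
  out <- data.frame(service = rep(services, each = Ml),
                    state = rep(seq_len(Ml), times = length(services)),
                    expected_cost = as.vector(t(acc)))
  structure(out, class = c("lifetime_cost_result", "data.frame"),
            years_by_state = years, sex = sex, year = year,
            entry_age = entry_age, scenario = model$spec$id,
            convention = convention)
}

#' Aggregate annual expenditure series from a projected population
#'
#' Per calendar year, the sum over age/sex/state cells of persons times the
#' expected annual cost, with the half-year death correction (persons dying
#' during the year accrue half a year of costs, recomputed from the same
#' scenario transition rows the projection used).
#'
#' @param trajectory A `population_trajectory`.
#' @param model The `scenario_model` the trajectory was projected under.
#' @param service Service name.
#' @param partner,education Representative covariate levels.
#' @return An `expenditure_series` data frame `year`, `amount`.
#' @export
aggregate_expenditures <- function(trajectory, model, service,
                                   partner = 1, education = 2) {
  params <- model$params
  cost_model(params, service)
  if (!identical(trajectory$scenario, model$spec$id))
    stop("trajectory was projected under scenario '", trajectory$scenario,
         "', not '", model$spec$id, "'")
  Ml <- params$n_living
  M <- params$n_states
  years <- as.integer(names(trajectory$states))
  amount <- numeric(length(years))
  for (yi in seq_along(years)) {
    st <- trajectory$states[[yi]]
    ages <- as.integer(dimnames(st$counts)$age)
    for (si in 1:2) {
      sex <- si - 1L
      df <- data.frame(sex = sex, partner = partner, age = ages,
                       education = education)
      Xc <- design_cost(df$sex, df$partner, df$age, df$education,
                        rep(years[yi], length(ages)), params$year_levels)
      for (m in seq_len(Ml)) {
        P <- scenario_rows_by_age(model, m, sex, ages, years[yi] + 1L,
                                  partner, education)
        ec <- plogis(drop(Xc %*% params$cost[[service]]$use[, m])) *
          exp(drop(Xc %*% params$cost[[service]]$mean[, m]))
        w <- st$counts[, si, m] * (1 - 0.5 * P[, M])
        amount[yi] <- amount[yi] + sum(w * ec)
      }
    }
  }
  structure(data.frame(year = years, amount = amount),
            class = c("expenditure_series", "data.frame"),
            service = service, scenario = model$spec$id)
}

#' Geometric-mean annual growth rate of an expenditure series
#'
#' `((end / start)^(1 / span) - 1) * 100`, the constant annual growth rate
#' that carries the first year's amount to the last year's.
#'
#' @param series An `expenditure_series` (or data frame `year`, `amount`).
#' @return Percent per year.
#' @export
annual_growth_rate <- function(series) {
  n <- nrow(series)
  start <- series$amount[1L]
  end <- series$amount[n]
  if (start <= 0 || end <= 0)
    stop("growth rate undefined for non-positive endpoints")
  span <- series$year[n] - series$year[1L]
  ((end / start)^(1 / span) - 1) * 100
}

#' Write the full scenario report bundle
#'
#' For every calibrated scenario (plus the baseline) writes three
#' perspectives to `out_dir`: a table of state-decomposed remaining life
#' expectancy and lifetime costs at 65 in 2050 by sex; population pyramid
#' tables for 2010 and 2050; and aggregate expenditure series per service
#' with geometric annual growth rates. A JSON manifest records scenario
#' ids, calibrated rates, the model fingerprint and the seed.
#'
#' @param specs Named list of `scenario_spec` (calibrated where
#'   applicable); uncalibrated scenarios are skipped with a warning.
#' @param params A labeled `latent_params` with all cost models.
#' @param out_dir Output directory (created if missing).
#' @param inputs Population inputs as [default_population_inputs()].
#' @param seed Seed recorded in the manifest (the computation itself is
#'   deterministic).
#' @return Invisibly, the manifest as a list.
#' @export
report_bundle <- function(specs, params, out_dir,
                          inputs = default_population_inputs(),
                          seed = NULL) {
  if (inherits(params, "health_fit")) params <- params$params
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  usable <- character(0)
  for (id in names(specs)) {
    sp <- specs[[id]]
    if (sp$hypothesis != "baseline" && length(sp$rates) < 2L) {
      warning("scenario '", id, "' is not calibrated; skipped")
      next
    }
    usable <- c(usable, id)
  }
  le_rows <- list(); growth_rows <- list(); series_rows <- list()
  pyr_rows <- list()
  for (id in usable) {
    mod <- scenario_model(params, specs[[id]])
    for (sex in c(0, 1)) {
      lt <- remaining_life_expectancy(mod, sex)
      lc <- lifetime_costs(mod, sex)
      le_rows[[paste(id, sex)]] <- data.frame(
        scenario = id, sex = sex,
        state = seq_along(lt$by_state),
        years = lt$by_state,
        t(matrix(lc$expected_cost, nrow = length(lt$by_state),
                 dimnames = list(NULL, unique(lc$service)))))
    }
    init <- init_population(inputs$stock, model_state_shares(params),
                            n_living = params$n_living)
    traj <- project(init, inputs$entrants, mod)
    for (yr in c(2010, 2050)) {
      p <- pyramid(traj, yr)
      p$scenario <- id; p$year <- yr
      pyr_rows[[paste(id, yr)]] <- p
    }
    for (s in names(params$cost)) {
      ser <- aggregate_expenditures(traj, mod, s)
      ser$scenario <- id; ser$service <- s
      series_rows[[paste(id, s)]] <- as.data.frame(ser)
      growth_rows[[paste(id, s)]] <- data.frame(
        scenario = id, service = s,
        growth_pct_per_year = annual_growth_rate(ser))
    }
  }
  files <- list(
    lifetime = file.path(out_dir, "lifetime_le_costs.csv"),
    pyramids = file.path(out_dir, "pyramids.csv"),
    series = file.path(out_dir, "expenditure_series.csv"),
    growth = file.path(out_dir, "growth_rates.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write.csv(do.call(rbind, le_rows), files$lifetime, row.names = FALSE)
  write.csv(do.call(rbind, pyr_rows), files$pyramids, row.names = FALSE)
  write.csv(do.call(rbind, series_rows), files$series, row.names = FALSE)
  write.csv(do.call(rbind, growth_rows), files$growth, row.names = FALSE)
  manifest <- list(
    scenarios = lapply(specs[usable], function(sp) list(
      id = sp$id, hypothesis = sp$hypothesis,
      uses_initial_ramp = sp$uses_initial_ramp,
      rates = if (sp$hypothesis == "baseline") "not-applicable" else
        lapply(sp$rates, function(r)
          r[c("x", "x_poor_death", "achieved_le", "target")]))),
    model_fingerprint = params_fingerprint(params),
    seed = seed,
    files = files
  )
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
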