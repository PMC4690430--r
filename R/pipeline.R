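#' Default end-to-end run configuration
#'
#' All settings of the simulate - fit - calibrate - project - report
#' pipeline in one list: panel design and size, estimation settings,
#' scenario list with life-expectancy targets, population inputs, seeds and
#' output paths. Defaults encode the study setup: four latent states, a
#' 1995-2007 estimation panel, projection 2010-2050 with entry at 65, and
#' 2050 LE targets 21.1/24.6 (standard) and 24.1/27.6 (optimistic).
#' Round-trips losslessly through JSON.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seeds = list(truth = 1L, panel = 20L, fit = 300L),
    panel = list(n = 2000L, design = list()),
    fit = list(n_living = 3L, tol = 1e-7, max_iter = 500L,
               n_restarts = 1L),
    scenarios = c("baseline", "1o", "1++", "2o", "2+", "2++",
                  "3o", "3+", "3++"),
    lifetable = list(age_cap = 110L, half_year = TRUE),
    population = list(stock_count = 100, entrant_count = 100),
    out_dir = "healthmarkov-run"
  )
  overrides <- list(...)
  modifyList(cfg, overrides)
}

#' Write / read a run configuration
#' @param config A `run_config` list.
#' @param path File path (JSON).
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
}

#' Run the full pipeline: simulate, fit, calibrate, project, report
#'
#' Stages: (1) build the seeded synthetic truth and simulate the scheduled
#' estimation panel (written as CSV, truth as JSON); (2) fit the latent
#' Markov model by EM, attach the ex-post home-care and LTC cost models,
#' and order the states (fitted model written as JSON); (3) calibrate the
#' requested scenarios per sex, project the population 2010-2050 under
#' each, and write the report bundle. Each stage's outputs land in
#' `config$out_dir`; the whole run is deterministic given the configured
#' seeds.
#'
#' @param config A [default_config()] list.
#' @param stages Subset of `c("simulate", "fit", "scenarios")` to run.
#' @param verbose Print stage progress.
#' @return List with the objects produced (`truth`, `panel`, `fit`,
#'   `specs`, `manifest`, `paths`).
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "fit", "scenarios"),
                         verbose = TRUE) {
  out <- list(paths = list())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  design <- do.call(panel_design, config$panel$design)
  truth <- make_default_truth(config$seeds$truth,
                              year_levels = design$start_year:design$end_year)

  if ("simulate" %in% stages) {
    say("simulate: n = ", config$panel$n, ", seed = ", config$seeds$panel)
    panel <- simulate_panel(truth, config$panel$n, design,
                            seed = config$seeds$panel)
    out$paths$panel <- file.path(config$out_dir, "panel.csv")
    out$paths$truth <- file.path(config$out_dir, "truth.json")
    write_panel(panel, out$paths$panel)
    write_params(truth, out$paths$truth)
    say("simulate: truth fingerprint ", params_fingerprint(truth))
    out$truth <- truth
    out$panel <- panel
  }

  if ("fit" %in% stages) {
    panel <- out$panel %||% read_panel(file.path(config$out_dir,
                                                 "panel.csv"))
    say("fit: EM with ", config$fit$n_living, " living states")
    fit <- fit_em(panel, n_living = config$fit$n_living,
                  tol = config$fit$tol, max_iter = config$fit$max_iter,
                  n_restarts = config$fit$n_restarts,
                  seed = config$seeds$fit, verbose = verbose)
    if (!fit$converged)
      stop("EM did not converge within ", config$fit$max_iter,
           " iterations")
    fit <- label_states(fit)
    fit <- add_expost_costs(fit, panel)
    out$paths$model <- file.path(config$out_dir, "fitted_model.json")
    write_params(fit$params, out$paths$model)
    out$fit <- fit
  }

  if ("scenarios" %in% stages) {
    params <- if (!is.null(out$fit)) out$fit$params else
      read_params(file.path(config$out_dir, "fitted_model.json"))
    specs <- scenario_set()[config$scenarios]
    for (id in names(specs)) {
      if (specs[[id]]$hypothesis == "baseline") next
      for (sex in c(0, 1)) {
        specs[[id]] <- calibrate(params, specs[[id]], sex,
                                 age_cap = config$lifetable$age_cap,
                                 half_year = config$lifetable$half_year)
        r <- scenario_rates(specs[[id]], sex)
        say(sprintf(
          "calibrate %s (%s): x = %.5f%s, LE = %.3f (target %.1f)",
          id, if (sex == 0) "men" else "women", r$x,
          if (!is.null(r$x_poor_death))
            sprintf(", x_poor_death = %.5f", r$x_poor_death) else "",
          r$achieved_le, r$target))
      }
    }
    inputs <- default_population_inputs(config$population$stock_count,
                                        config$population$entrant_count)
    out$manifest <- report_bundle(specs, params,
                                  file.path(config$out_dir, "report"),
                                  inputs = inputs,
                                  seed = config$seeds$truth)
    out$specs <- specs
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
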