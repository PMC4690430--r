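#' Ex-post two-part cost model for a registry-window service
#'
#' Home-care and institutional LTC costs are observed only inside a late
#' registry window, so they do not enter the joint likelihood. Their
#' relationship to the latent state is estimated ex post: a two-part
#' (logit + Gamma GLM) model per living state, fitted by
#' posterior-probability-weighted likelihood on the individual-years inside
#' the service's observation window, with the smoothed state probabilities
#' from the converged hospital-and-indicator fit as weights.
#'
#' @param panel A `health_panel` whose schedule contains the service's
#'   window.
#' @param posteriors Data frame from [posterior_states()] (columns `id`,
#'   `year`, `gamma_1..gamma_M`), row-aligned with `panel` by id and year.
#' @param service `"homecare"` or `"ltc"`.
#' @return Cost-model block (`use`, `mean`, `shape`) in `latent_params`
#'   format.
#' @export
fit_expost_cost_model <- function(panel, posteriors, service) {
  df <- as.data.frame(panel)
  col <- paste0("cost_", service)
  obs <- which(!is.na(df[[col]]))
  if (!length(obs))
    stop("no observed ", service, " costs in the panel (empty window?)")
  key_df <- paste(df$id, df$year)
  key_post <- paste(posteriors$id, posteriors$year)
  ix <- match(key_df[obs], key_post)
  if (anyNA(ix)) stop("posteriors do not cover all observed records")
  gcols <- grep("^gamma_", names(posteriors), value = TRUE)
  Ml <- length(gcols) - 1L
  gamma <- as.matrix(posteriors[ix, gcols[seq_len(Ml)], drop = FALSE])

  sched <- panel_schedule(panel)
  year_levels <- sched$start_year:sched$end_year
  dfo <- df[obs, ]
  Xc <- design_cost(dfo$sex, dfo$partner, dfo$age, dfo$education, dfo$year,
                    year_levels)
  use <- mean_ <- matrix(0, ncol(Xc), Ml)
  parts <- vector("list", Ml)
  for (m in seq_len(Ml)) {
    fit <- fit_two_part_state(Xc, dfo[[col]], gamma[, m])
    use[, m] <- fit$use
    mean_[, m] <- fit$mean
    parts[[m]] <- fit
  }
  ## calendar-year dummies outside the window are inestimable; pin them to
  ## the reference level so the model extrapolates with window-average costs
  use[!is.finite(use)] <- 0
  mean_[!is.finite(mean_)] <- 0
  shape <- gamma_shape_ml(unlist(lapply(parts, `[[`, "cost")),
                          unlist(lapply(parts, `[[`, "mu")),
                          unlist(lapply(parts, `[[`, "w")))
  list(use = use, mean = mean_, shape = shape)
}

#' Attach ex-post cost models to a fitted model
#'
#' Convenience wrapper: computes posteriors from the fit, runs
#' [fit_expost_cost_model()] for each requested service, and returns the
#' fit with the cost models attached to its parameters.
#'
#' @param fit A converged `health_fit`.
#' @param panel The estimation panel.
#' @param services Services to fit ex post.
#' @return The `health_fit` with extended `params$cost`.
#' @export
add_expost_costs <- function(fit, panel, services = c("homecare", "ltc")) {
  post <- posterior_states(fit, panel)
  for (s in services)
    fit$params$cost[[s]] <- fit_expost_cost_model(panel, post, s)
  validate_params(fit$params)
  fit
}
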