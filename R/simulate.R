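#' Sampling design for a synthetic survey-registry panel
#'
#' Describes the panel window, the entry-age design, covariate sampling, the
#' survey wave schedule and the per-service registry windows. Defaults
#' emulate a 1995-2007 panel of older adults with entry ages uniform on
#' 55-85, triennial health-indicator waves starting in the first panel year,
#' annual hospital cost registration over the whole window, and home-care /
#' LTC cost registration only in 2004-2007, plus one refreshment cohort
#' (entry ages 55-64) in 2002.
#'
#' @param start_year,end_year Panel calendar window.
#' @param entry_age_range Entry ages (uniform) for the initial cohort.
#' @param survey_interval Years between indicator waves (first wave in
#'   `start_year`).
#' @param windows Named list of `c(first, last)` calendar-year registry
#'   windows per service.
#' @param refresh_year Calendar year of the refreshment cohort (`NA` for
#'   none).
#' @param refresh_frac Size of the refreshment cohort relative to `n`.
#' @param refresh_age_range Entry ages for the refreshment cohort.
#' @param female_share,partner_prob,educ_probs Covariate sampling: share of
#'   women, probability of having a partner, and probabilities of the three
#'   education levels.
#' @return A list of class `panel_design`.
#' @export
panel_design <- function(start_year = 1995L, end_year = 2007L,
                         entry_age_range = c(55L, 85L),
                         survey_interval = 3L,
                         windows = list(hospital = c(1995L, 2007L),
                                        homecare = c(2004L, 2007L),
                                        ltc = c(2004L, 2007L)),
                         refresh_year = 2002L, refresh_frac = 1/3,
                         refresh_age_range = c(55L, 64L),
                         female_share = 0.5, partner_prob = 0.7,
                         educ_probs = c(0.3, 0.45, 0.25)) {
  structure(list(start_year = start_year, end_year = end_year,
                 entry_age_range = entry_age_range,
                 survey_interval = survey_interval, windows = windows,
                 refresh_year = refresh_year, refresh_frac = refresh_frac,
                 refresh_age_range = refresh_age_range,
                 female_share = female_share, partner_prob = partner_prob,
                 educ_probs = educ_probs),
            class = "panel_design")
}

validate_profile <- function(profile) {
  need <- c("sex", "partner", "age", "education", "entry_year")
  miss <- setdiff(need, names(profile))
  if (length(miss))
    stop("profile is missing fields: ", paste(miss, collapse = ", "))
  if (profile$age < 55 || profile$age > 110)
    stop("entry age must lie in [55, 110], got ", profile$age)
  if (!profile$sex %in% c(0, 1)) stop("sex must be 0 (male) or 1 (female)")
  if (!profile$partner %in% c(0, 1)) stop("partner must be 0 or 1")
  if (!profile$education %in% 1:3) stop("education must be 1, 2 or 3")
  invisible(profile)
}

#' Simulate one individual's panel records from the latent model
#'
#' Samples the latent path (initial-state model, then annual transition
#' logits with origin-year covariates), then the emissions: all seven
#' indicator categories and annual costs for every service with a fitted
#' cost model. Records stop at death; the death-year record carries
#' `vital_status = "dead"` and no emissions (death is observed through vital
#' status alone). Uses the current RNG stream.
#'
#' @param params A `latent_params` object (truth).
#' @param profile List with `sex` (0/1), `partner` (0/1), `age`,
#'   `education` (1-3), `entry_year`.
#' @param horizon Maximum number of annual records (>= 1).
#' @return A data frame, one row per individual-year, with the true latent
#'   `state` column included (downstream masking removes it).
#' @export
simulate_individual <- function(params, profile, horizon) {
  validate_profile(profile)
  stopifnot(horizon >= 1)
  M <- params$n_states
  scheme <- params$indicators
  state <- sample.int(params$n_living, 1L,
                      prob = initial_state_probs(params, profile$age,
                                                 profile$sex))
  rows <- vector("list", horizon)
  for (t in seq_len(horizon)) {
    year <- profile$entry_year + t - 1L
    age <- profile$age + t - 1L
    if (state == M) {
      rows[[t]] <- one_record(profile, year, age, state = M,
                              y = rep(NA_integer_, length(scheme)),
                              costs = rep(NA_real_, length(SERVICES)),
                              vital = "dead")
      rows <- rows[seq_len(t)]
      break
    }
    y <- vapply(seq_along(scheme), function(j)
      sample.int(scheme[[j]], 1L, prob = indicator_prob(params, state, j)),
      integer(1L))
    covs <- list(sex = profile$sex, partner = profile$partner, age = age,
                 education = profile$education)
    costs <- vapply(SERVICES, function(s) {
      if (is.null(params$cost[[s]])) return(NA_real_)
      p <- cost_use_prob(params, state, covs, s, year)
      if (rbinom(1L, 1L, p) == 0L) return(0)
      mu <- cost_mean(params, state, covs, s, year)
      shape <- params$cost[[s]]$shape
      rgamma(1L, shape = shape, rate = shape / mu)
    }, numeric(1L))
    rows[[t]] <- one_record(profile, year, age, state, y, costs, "alive")
    if (t == horizon) break
    state <- sample.int(M, 1L, prob = transition_row(params, state, covs))
  }
  do.call(rbind, rows)
}

one_record <- function(profile, year, age, state, y, costs, vital) {
  out <- data.frame(id = NA_integer_, year = year, sex = profile$sex,
                    partner = profile$partner, age = age,
                    education = profile$education)
  for (j in seq_along(y)) out[[paste0("y", j)]] <- y[j]
  for (k in seq_along(SERVICES)) out[[paste0("cost_", SERVICES[k])]] <-
    costs[k]
  out$state <- state
  out$vital_status <- vital
  out
}

#' Simulate a full panel dataset
#'
#' Simulates `n` individuals entering at the panel start plus a refreshment
#' cohort at the design's refreshment year, then (optionally) applies the
#' observation schedule: indicators kept only in survey years, each
#' service's costs kept only inside its registry window.
#'
#' @param params Truth parameters.
#' @param n Number of individuals in the initial cohort (>= 0).
#' @param design A [panel_design()].
#' @param seed Integer seed (the global RNG is set once from it).
#' @param apply_schedule Mask emissions by the observation schedule
#'   (default) or return the fully observed panel.
#' @param keep_latent Keep the true latent `state` column (only possible for
#'   unscheduled panels).
#' @return A `health_panel`: a data frame with schedule metadata attached.
#' @export
simulate_panel <- function(params, n, design = panel_design(), seed = 1L,
                           apply_schedule = TRUE, keep_latent = FALSE) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  horizon0 <- design$end_year - design$start_year + 1L
  draw_profile <- function(age_range, entry_year) {
    list(sex = as.numeric(runif(1) < design$female_share),
         partner = as.numeric(runif(1) < design$partner_prob),
         age = sample(seq(age_range[1L], age_range[2L]), 1L),
         education = sample(1:3, 1L, prob = design$educ_probs),
         entry_year = entry_year)
  }
  blocks <- list()
  idx <- 0L
  sim_cohort <- function(n_c, age_range, entry_year, horizon) {
    lapply(seq_len(n_c), function(i) {
      df <- simulate_individual(params, draw_profile(age_range, entry_year),
                                horizon)
      df$id <- idx + i
      df
    })
  }
  if (n > 0) {
    blocks <- sim_cohort(n, design$entry_age_range, design$start_year,
                         horizon0)
    idx <- n
  }
  n_refresh <- if (is.na(design$refresh_year)) 0L else
    as.integer(round(n * design$refresh_frac))
  if (n_refresh > 0) {
    blocks <- c(blocks, sim_cohort(n_refresh, design$refresh_age_range,
                                   design$refresh_year,
                                   design$end_year - design$refresh_year + 1L))
  }
  df <- if (length(blocks)) do.call(rbind, blocks) else
    one_record(list(sex = 0, partner = 0, age = 65, education = 2),
               design$start_year, 65, 1L,
               rep(NA_integer_, length(params$indicators)),
               rep(NA_real_, length(SERVICES)), "alive")[0L, ]
  rownames(df) <- NULL
  panel <- as_health_panel(df, design, params$indicators)
  if (apply_schedule)
    panel <- apply_observation_schedule(panel, design$survey_interval,
                                        design$windows)
  if (!keep_latent) panel$state <- NULL
  panel
}

as_health_panel <- function(df, design, scheme) {
  survey_years <- seq(design$start_year, design$end_year,
                      by = design$survey_interval)
  structure(df, class = c("health_panel", "data.frame"),
            schedule = list(survey_years = survey_years,
                            windows = design$windows,
                            start_year = design$start_year,
                            end_year = design$end_year),
            indicators = scheme)
}

#' Schedule metadata of a panel
#' @param panel A `health_panel`.
#' @return List with `survey_years`, per-service `windows`, and the panel
#'   window.
#' @export
panel_schedule <- function(panel) attr(panel, "schedule")

#' Mask a panel to its observation schedule
#'
#' Indicators are kept only in survey years (death-year records carry no
#' indicator emissions in any case: death is observed via vital status);
#' each service's costs are kept only inside that service's registry window.
#' The true latent state column, if present, is dropped.
#'
#' @param panel A `health_panel` (fully or partially observed).
#' @param survey_interval Years between indicator waves, counted from the
#'   panel start year.
#' @param registry_windows Named list of `c(first, last)` years per service.
#' @return The masked `health_panel`, with updated schedule metadata.
#' @export
apply_observation_schedule <- function(panel, survey_interval,
                                       registry_windows) {
  sched <- panel_schedule(panel)
  yrs <- c(sched$start_year, sched$end_year)
  for (s in names(registry_windows)) {
    w <- registry_windows[[s]]
    if (w[1L] < yrs[1L] || w[2L] > yrs[2L])
      stop("registry window for ", s, " (", w[1L], "-", w[2L],
           ") lies outside the panel years ", yrs[1L], "-", yrs[2L])
  }
  survey_years <- seq(yrs[1L], yrs[2L], by = survey_interval)
  scheme <- attr(panel, "indicators")
  off_wave <- !(panel$year %in% survey_years)
  for (j in seq_along(scheme))
    panel[[paste0("y", j)]][off_wave] <- NA_integer_
  for (s in names(registry_windows)) {
    w <- registry_windows[[s]]
    col <- paste0("cost_", s)
    if (!col %in% names(panel)) next
    outside <- panel$year < w[1L] | panel$year > w[2L]
    panel[[col]][outside] <- NA_real_
  }
  panel$state <- NULL
  attr(panel, "schedule") <- list(survey_years = survey_years,
                                  windows = registry_windows,
                                  start_year = yrs[1L], end_year = yrs[2L])
  panel
}

#' Write / read a panel as delimited text
#'
#' Plain CSV, one individual-year per row, missing values as empty fields,
#' with the observation-schedule metadata in `#`-prefixed header lines so
#' the round trip is lossless.
#'
#' @param panel A `health_panel`.
#' @param path File path.
#' @return `read_panel` returns a `health_panel`; `write_panel` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  sched <- panel_schedule(panel)
  scheme <- attr(panel, "indicators")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# healthmarkov-panel-1"),
    paste0("# years: ", sched$start_year, "-", sched$end_year),
    paste0("# survey_years: ", paste(sched$survey_years, collapse = ",")),
    vapply(names(sched$windows), function(s)
      paste0("# window_", s, ": ", sched$windows[[s]][1L], "-",
             sched$windows[[s]][2L]), character(1L)),
    paste0("# indicators: ",
           paste0(names(scheme), "=", scheme, collapse = ","))
  ), con)
  df <- as.data.frame(panel)
  df$state <- NULL
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

parse_range <- function(x) as.integer(strsplit(x, "-", fixed = TRUE)[[1L]])

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  if (!length(meta) || meta[1L] != "# healthmarkov-panel-1")
    stop("not a healthmarkov panel file: ", path)
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(ln)) stop("panel file is missing metadata field '", key, "'")
    sub(paste0("^# ", key, ": "), "", ln[1L])
  }
  yrs <- parse_range(get_meta("years"))
  survey_years <- as.integer(strsplit(get_meta("survey_years"), ",")[[1L]])
  win_keys <- sub("^# window_([a-z]+):.*$", "\\1",
                  grep("^# window_", meta, value = TRUE))
  windows <- lapply(win_keys, function(s) parse_range(get_meta(paste0(
    "window_", s))))
  names(windows) <- win_keys
  ind_spec <- strsplit(strsplit(get_meta("indicators"), ",")[[1L]], "=")
  scheme <- setNames(vapply(ind_spec, function(x) as.integer(x[2L]),
                            integer(1L)),
                     vapply(ind_spec, `[`, character(1L), 1L))
  df <- read.csv(path, comment.char = "#", na.strings = "",
                 stringsAsFactors = FALSE)
  validate_panel_df(df, scheme)
  design <- panel_design(start_year = yrs[1L], end_year = yrs[2L],
                         survey_interval = if (length(survey_years) > 1L)
                           survey_years[2L] - survey_years[1L] else 1L,
                         windows = windows)
  panel <- as_health_panel(df, design, scheme)
  attr(panel, "schedule")$survey_years <- survey_years
  panel
}

validate_panel_df <- function(df, scheme) {
  need <- c("id", "year", "sex", "partner", "age", "education",
            paste0("y", seq_along(scheme)), paste0("cost_", SERVICES),
            "vital_status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel file is missing columns: ", paste(miss, collapse = ", "))
  key <- paste(df$id, df$year)
  if (anyDuplicated(key)) {
    r <- which(duplicated(key))[1L]
    stop("duplicated individual-year key at row ", r, " (id=", df$id[r],
         ", year=", df$year[r], ")")
  }
  for (s in SERVICES) {
    col <- paste0("cost_", s)
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      stop("negative cost at row ", bad[1L], ", column ", col)
  }
  for (j in seq_along(scheme)) {
    col <- paste0("y", j)
    bad <- which(!is.na(df[[col]]) &
                   (df[[col]] < 1 | df[[col]] > scheme[[j]]))
    if (length(bad))
      stop("indicator category out of range at row ", bad[1L],
           ", column ", col)
  }
  if (!all(df$vital_status %in% c("alive", "dead")))
    stop("vital_status must be 'alive' or 'dead'")
  ## no records after a death record
  dead <- df[df$vital_status == "dead", c("id", "year")]
  if (nrow(dead)) {
    last <- tapply(df$year, df$id, max)
    bad <- dead$id[dead$year < last[as.character(dead$id)]]
    if (length(bad))
      stop("records exist after death for id ", bad[1L])
  }
  invisible(df)
}
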