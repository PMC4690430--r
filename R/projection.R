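## Ages tracked in the projection: 65 up to (but excluding) the cap.
proj_ages <- function(age_cap = 110) 65:(age_cap - 1L)

#' Bundled synthetic population inputs
#'
#' Flat default inputs for the projection: a 2010 stock of `stock_count`
#' persons per age (65-95) and sex, and `entrant_count` new 65-year-olds
#' per sex per year 2011-2050. Counts are in abstract person units; real
#' applications supply their own tables.
#'
#' @param stock_count Persons per age/sex cell in 2010.
#' @param entrant_count New 65-year-olds per sex per year.
#' @return List with data frames `stock` (age, sex, count) and `entrants`
#'   (year, sex, count).
#' @export
default_population_inputs <- function(stock_count = 100,
                                      entrant_count = 100) {
  list(
    stock = expand.grid(age = 65:95, sex = c(0, 1), count = stock_count),
    entrants = expand.grid(year = 2011:2050, sex = c(0, 1),
                           count = entrant_count)
  )
}

#' State-share function from a fitted model
#'
#' Age- and sex-specific living-state shares from the model's initial-state
#' logit, for allocating population counts to health states.
#'
#' @param params A labeled `latent_params`.
#' @return Function `(age, sex)` returning shares over living states.
#' @export
model_state_shares <- function(params) {
  function(age, sex) initial_state_probs(params, age, sex)
}

#' Initialize a projected population state
#'
#' Allocates age/sex population counts to living health states by the given
#' shares. Fractional persons are allowed (the projection is an
#' expected-value calculation).
#'
#' @param counts Data frame with `age`, `sex` (0/1), `count`.
#' @param shares Function `(age, sex)` returning living-state shares
#'   (summing to 1), e.g. [model_state_shares()].
#' @param n_living Number of living states.
#' @param year Calendar year of the state.
#' @param age_cap Terminal age of the projection.
#' @return A `population_state`: counts array age x sex x state plus death
#'   accounting.
#' @export
init_population <- function(counts, shares, n_living = 3L, year = 2010,
                            age_cap = 110) {
  ages <- proj_ages(age_cap)
  C <- array(0, c(length(ages), 2L, n_living),
             dimnames = list(age = ages, sex = c("male", "female"),
                             state = seq_len(n_living)))
  for (r in seq_len(nrow(counts))) {
    a <- counts$age[r]
    if (!a %in% ages) stop("age ", a, " outside the projected range")
    sh <- shares(a, counts$sex[r])
    if (abs(sum(sh) - 1) > 1e-8)
      stop("state shares must sum to 1 (age ", a, ", sex ",
           counts$sex[r], ")")
    si <- counts$sex[r] + 1L
    C[as.character(a), si, ] <- C[as.character(a), si, ] +
      counts$count[r] * sh
  }
  structure(list(year = as.integer(year), counts = C,
                 cum_deaths = c(male = 0, female = 0),
                 deaths_step = c(male = 0, female = 0),
                 age_cap = age_cap),
            class = "population_state")
}

#' Total living persons in a population state
#' @param pop A `population_state`.
#' @return Sum of all age/sex/state cells.
#' @export
total_alive <- function(pop) sum(pop$counts)

## Scenario transition rows for a vector of ages (one origin, one sex).
scenario_rows_by_age <- function(model, origin, sex, ages, year,
                                 partner = 1, education = 2) {
  df <- data.frame(sex = sex, partner = partner, age = ages,
                   education = education)
  P <- transition_rows_df(model$params, origin, df)
  M <- model$params$n_states
  P <- cbind(P)
  for (i in seq_along(ages))
    P[i, ] <- adjust_row(model, P[i, ], origin, sex, year)
  P
}

#' Advance a projected population by one year
#'
#' Redistributes every age/sex/state cell by the scenario transition row
#' for that cell (calendar year of the step's destination), advances ages
#' by one, accumulates deaths, and removes survivors reaching the age cap
#' to deaths. Entrants are handled by [project()].
#'
#' @param pop A `population_state`.
#' @param model A `scenario_model`.
#' @param partner,education Representative covariate levels.
#' @return The `population_state` for the following year.
#' @export
step_year <- function(pop, model, partner = 1, education = 2) {
  ages <- proj_ages(pop$age_cap)
  Ml <- dim(pop$counts)[3L]
  M <- Ml + 1L
  new_year <- pop$year + 1L
  newC <- array(0, dim(pop$counts), dimnames = dimnames(pop$counts))
  deaths <- c(male = 0, female = 0)
  for (si in 1:2) {
    sex <- si - 1L
    inflow <- array(0, c(length(ages), Ml))  # by origin age index
    for (m in seq_len(Ml)) {
      P <- scenario_rows_by_age(model, m, sex, ages, new_year,
                                partner, education)
      v <- pop$counts[, si, m]
      inflow <- inflow + v * P[, seq_len(Ml), drop = FALSE]
      deaths[si] <- deaths[si] + sum(v * P[, M])
    }
    ## ages advance: origin age a contributes to age a+1; the last age
    ## group's survivors pass the cap and are removed to deaths
    newC[-1L, si, ] <- inflow[-length(ages), , drop = FALSE]
    deaths[si] <- deaths[si] + sum(inflow[length(ages), ])
  }
  structure(list(year = new_year, counts = newC,
                 cum_deaths = pop$cum_deaths + deaths,
                 deaths_step = deaths, age_cap = pop$age_cap),
            class = "population_state")
}

#' Project the older population under a scenario, 2010-2050
#'
#' Deterministic expected-value cohort-component projection: the 2010
#' population stock is advanced year by year through the scenario-adjusted
#' transition model, and each year a new cohort of 65-year-olds enters with
#' the scenario's (possibly ramped) initial health profile.
#'
#' @param initial A `population_state` for the base year (see
#'   [init_population()]).
#' @param entrants Data frame `year`, `sex`, `count` of new 65-year-olds.
#' @param model A calibrated (or baseline) `scenario_model`.
#' @param end_year Final projected year.
#' @param partner,education Representative covariate levels.
#' @return A `population_trajectory`: list of yearly states plus
#'   provenance.
#' @export
project <- function(initial, entrants, model, end_year = 2050,
                    partner = 1, education = 2) {
  states <- list()
  states[[as.character(initial$year)]] <- initial
  pop <- initial
  params <- model$params
  while (pop$year < end_year) {
    pop <- step_year(pop, model, partner, education)
    ent <- entrants[entrants$year == pop$year, , drop = FALSE]
    for (r in seq_len(nrow(ent))) {
      prof <- initial_profile(model$spec, min(pop$year, 2050),
                              baseline_profile_at(params, ent$sex[r], 65))
      si <- ent$sex[r] + 1L
      pop$counts["65", si, ] <- pop$counts["65", si, ] +
        ent$count[r] * prof
      pop$entrants_step <- (if (is.null(pop$entrants_step)) 0 else
        pop$entrants_step) + ent$count[r]
    }
    states[[as.character(pop$year)]] <- pop
  }
  structure(list(states = states, scenario = model$spec$id,
                 base_year = model$base_year,
                 model_fingerprint = params_fingerprint(params)),
            class = "population_trajectory")
}

params_fingerprint <- function(params) {
  v <- c(unlist(params$trans), unlist(params$init),
         unlist(params$emission), unlist(lapply(params$cost, unlist)))
  sprintf("%.8e", sum(v * seq_along(v) %% 97))
}

#' Yearly totals of a trajectory
#' @param trajectory A `population_trajectory`.
#' @return Data frame `year`, `sex`, `state`, `persons`.
#' @export
trajectory_totals <- function(trajectory) {
  do.call(rbind, lapply(trajectory$states, function(s) {
    tot <- apply(s$counts, c(2L, 3L), sum)
    data.frame(year = s$year,
               sex = rep(c(0, 1), times = ncol(tot)),
               state = rep(seq_len(ncol(tot)), each = 2L),
               persons = as.vector(tot))
  }))
}

#' Write a trajectory as a long CSV with a JSON provenance sidecar
#'
#' One row per year, sex, age and living state; the sidecar
#' (`<path>.json`) records the scenario id, base year and model
#' fingerprint.
#'
#' @param trajectory A `population_trajectory`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  rows <- do.call(rbind, lapply(trajectory$states, function(s) {
    ages <- as.integer(dimnames(s$counts)$age)
    grid <- expand.grid(age = ages, sex = c(0, 1),
                        state = seq_len(dim(s$counts)[3L]))
    grid$year <- s$year
    grid$persons <- as.vector(s$counts)
    grid[, c("year", "sex", "age", "state", "persons")]
  }))
  write.csv(rows, path, row.names = FALSE)
  jsonlite::write_json(list(scenario = trajectory$scenario,
                            base_year = trajectory$base_year,
                            model_fingerprint =
                              trajectory$model_fingerprint),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Population pyramid by age bin, sex and health state
#'
#' @param trajectory A `population_trajectory`.
#' @param year Year in the trajectory.
#' @param bin_width Age bin width in years.
#' @return Data frame `age_bin`, `age_lo`, `sex`, `state`, `persons`.
#' @export
pyramid <- function(trajectory, year, bin_width = 5L) {
  s <- trajectory$states[[as.character(year)]]
  if (is.null(s)) stop("year ", year, " not in trajectory")
  ages <- as.integer(dimnames(s$counts)$age)
  lo <- 65L + bin_width * ((ages - 65L) %/% bin_width)
  out <- expand.grid(age_lo = sort(unique(lo)), sex = c(0, 1),
                     state = seq_len(dim(s$counts)[3L]))
  out$persons <- mapply(function(a, sx, st)
    sum(s$counts[lo == a, sx + 1L, st]), out$age_lo, out$sex, out$state)
  out$age_bin <- paste0(out$age_lo, "-", out$age_lo + bin_width - 1L)
  out[, c("age_bin", "age_lo", "sex", "state", "persons")]
}

#' Stochastic microsimulation of the projected population
#'
#' Individual-level counterpart of [project()], used as a Monte-Carlo
#' cross-check of the expected-value projection: state transitions are
#' drawn multinomially per age/sex/state cell, entrant states are drawn
#' from the scenario's initial profile, and annual costs are drawn from the
#' two-part models (death-year costs carry the same half-year weight as the
#' deterministic accounting). Counts are scaled so roughly `n_target`
#' individuals are simulated in total.
#'
#' @param model A `scenario_model`.
#' @param initial A `population_state` (fractional counts allowed; they are
#'   scaled and rounded to individuals).
#' @param entrants Data frame `year`, `sex`, `count`.
#' @param n_target Approximate total number of simulated individuals.
#' @param seed Integer seed.
#' @param end_year Final year.
#' @param services Services to accumulate expenditures for.
#' @param partner,education Representative covariate levels.
#' @return List with `scale` (simulated persons per projected person),
#'   `occupancy` (data frame year, sex, state, persons) and `expenditure`
#'   (data frame year, service, amount), both on the simulated scale.
#' @export
microsimulate_population <- function(model, initial, entrants,
                                     n_target = 50000L, seed = 1L,
                                     end_year = 2050,
                                     services = names(model$params$cost),
                                     partner = 1, education = 2) {
  set.seed(seed)
  params <- model$params
  Ml <- params$n_living
  total_in <- total_alive(initial) + sum(entrants$count)
  scale <- n_target / total_in
  ages <- proj_ages(initial$age_cap)
  C <- initial$counts * scale
  ## integerize cells
  C[] <- vapply(as.vector(C), function(x)
    floor(x) + rbinom(1L, 1L, x - floor(x)), numeric(1L))
  occ <- list(); exp_rows <- list()
  year <- initial$year
  record_occ <- function(C, year) {
    tot <- apply(C, c(2L, 3L), sum)
    data.frame(year = year, sex = rep(c(0, 1), ncol(tot)),
               state = rep(seq_len(ncol(tot)), each = 2L),
               persons = as.vector(tot))
  }
  occ[[1L]] <- record_occ(C, year)
  while (year < end_year) {
    year <- year + 1L
    newC <- array(0, dim(C), dimnames = dimnames(C))
    spend <- setNames(numeric(length(services)), services)
    for (si in 1:2) {
      sex <- si - 1L
      for (m in seq_len(Ml)) {
        P <- scenario_rows_by_age(model, m, sex, ages, year,
                                  partner, education)
        for (ai in seq_along(ages)) {
          n <- C[ai, si, m]
          if (n < 1) next
          moves <- drop(rmultinom(1L, n, P[ai, ]))
          died <- moves[Ml + 1L]
          if (ai < length(ages))
            newC[ai + 1L, si, ] <- newC[ai + 1L, si, ] +
              moves[seq_len(Ml)]
          covs <- list(sex = sex, partner = partner, age = ages[ai],
                       education = education)
          for (s in services) {
            p_use <- cost_use_prob(params, m, covs, s)
            mu <- cost_mean(params, m, covs, s)
            shp <- params$cost[[s]]$shape
            surv <- n - died
            u1 <- rbinom(1L, surv, p_use)
            u2 <- rbinom(1L, died, p_use)
            amt <- 0
            if (u1 > 0) amt <- amt + rgamma(1L, shape = shp * u1,
                                            rate = shp / mu)
            if (u2 > 0) amt <- amt + 0.5 * rgamma(1L, shape = shp * u2,
                                                  rate = shp / mu)
            spend[s] <- spend[s] + amt
          }
        }
      }
    }
    ent <- entrants[entrants$year == year, , drop = FALSE]
    for (r in seq_len(nrow(ent))) {
      n <- floor(ent$count[r] * scale)
      n <- n + rbinom(1L, 1L, ent$count[r] * scale - n)
      if (n < 1) next
      prof <- initial_profile(model$spec, min(year, 2050),
                              baseline_profile_at(params, ent$sex[r], 65))
      newC["65", ent$sex[r] + 1L, ] <- newC["65", ent$sex[r] + 1L, ] +
        drop(rmultinom(1L, n, prof))
    }
    C <- newC
    occ[[length(occ) + 1L]] <- record_occ(C, year)
    exp_rows[[length(exp_rows) + 1L]] <-
      data.frame(year = year - 1L, service = services,
                 amount = as.numeric(spend))
  }
  list(scale = scale, occupancy = do.call(rbind, occ),
       expenditure = do.call(rbind, exp_rows))
}
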