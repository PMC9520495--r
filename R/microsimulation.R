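# Microsimulation engine: forward simulation of each man's state
# sequence on the 28-day grid under the fitted cause-specific hazards,
# replicated (default 100x) to a 10-year (130-period) horizon.
#
# Occupancy is recorded at the START of each period; an event drawn
# during period t is tallied in period t and changes the state from
# period t+1 on. Under a constant hazard p this makes the cumulative
# incidence through period t exactly 1 - (1-p)^(t+1) and the expected
# number of occupied periods sum_t (1-m)^t — the closed forms the engine
# is verified against.

#' Microsimulation configuration
#'
#' @param replicates_per_individual replicate trajectories per man
#'   (default 100).
#' @param horizon_periods number of 28-day periods simulated (default
#'   130, i.e. 10 years).
#' @param seed master seed; per-(man, replicate) substreams make results
#'   independent of iteration order and population partitioning.
#' @param probability_overflow_policy what to do when cause-specific
#'   probabilities sum above 1 in a period: `"error"` (default) or
#'   `"rescale"` (divide all by the sum).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(replicates_per_individual = 100L,
                              horizon_periods = 130L,
                              seed = 1L,
                              probability_overflow_policy = c("error", "rescale")) {
  policy <- match.arg(probability_overflow_policy)
  stopifnot(replicates_per_individual >= 1, horizon_periods >= 1)
  structure(list(replicates_per_individual = as.integer(replicates_per_individual),
                 horizon_periods = as.integer(horizon_periods),
                 seed = as.integer(seed),
                 probability_overflow_policy = policy),
            class = "simulation_config")
}

# Per-transition probability lookup over the full covariate grid:
# array [risk_category 8, age_band 4, cci 4, tis_band 5].
.probability_array <- function(model) {
  if (is.null(model)) return(array(0, dim = c(8, 4, 4, 5)))
  grid <- expand.grid(risk_category = as.character(1:8), age_band = .AGE_BANDS,
                      cci = .CCI_LEVELS, time_in_state_band = .TIS_BANDS,
                      stringsAsFactors = FALSE)
  p <- predict_period_probability(model, grid)
  array(p, dim = c(8, 4, 4, 5))
}

# Draw CRPC categories for rows transitioning CSPC -> CRPC. `policy` is
# an 8x8 row-stochastic matrix P(CRPC category | CSPC category); NULL
# keeps the CSPC category.
.draw_crpc_category <- function(policy, cspc_cat, u) {
  if (is.null(policy)) return(cspc_cat)
  cum <- t(apply(policy, 1, cumsum))
  vapply(seq_along(cspc_cat), function(i) {
    1L + sum(u[i] > cum[cspc_cat[i], ])
  }, integer(1))
}

#' Run the 28-day microsimulation over a starting population
#'
#' Simulates every man `replicates_per_individual` times from his start
#' state. Each period, the cause-specific exit probabilities of the
#' current state are evaluated (CSPC: to CRPC, PCa death, other-cause
#' death; CRPC: PCa death, other-cause death) and one categorical
#' outcome is drawn with stay-probability `1 - sum(p)`. On a simulated
#' transition to CRPC the man receives a CRPC risk category drawn from
#' `crpc_category_policy` and his time-in-state clock resets; his age
#' band advances with simulated time throughout.
#'
#' @param population data.frame with one row per man: `patient_id`,
#'   `start_state` (`"CSPC"`/`"CRPC"`), `risk_category` (1..8),
#'   `age_years` (age at start), `cci`.
#' @param models named list of [fit_transition_model()] /
#'   [constant_transition_model()] objects under any of
#'   `cspc_to_crpc`, `cspc_to_pca_death`, `crpc_to_pca_death`; a missing
#'   entry means probability 0.
#' @param other_cause a `hazard_table` of per-28-day other-cause death
#'   probabilities.
#' @param config a [simulation_config()].
#' @param crpc_category_policy 8x8 row-stochastic matrix
#'   `P(CRPC category | CSPC category)`, or `NULL` to carry the CSPC
#'   category over.
#' @param keep_trajectories if `TRUE`, attach the full state-by-period
#'   matrix (rows = man x replicate) as attribute `trajectories`.
#' @return object of class `occupancy_summary`: list with `occupancy`
#'   (start_state, start_category, period, state, count), `events`
#'   (start_state, start_category, period, event, count), `strata`
#'   (stratum sizes), `replicates`, `horizon`.
#' @export
run_microsimulation <- function(population, models, other_cause,
                                config = simulation_config(),
                                crpc_category_policy = NULL,
                                keep_trajectories = FALSE) {
  if (nrow(population) == 0) {
    .crpc_error("crpcstates_no_data", "empty starting population")
  }
  stopifnot(all(population$start_state %in% c("CSPC", "CRPC")),
            all(population$risk_category %in% 1:8),
            all(population$cci %in% .CCI_LEVELS))
  reps <- config$replicates_per_individual
  horizon <- config$horizon_periods

  a_crpc <- .probability_array(models$cspc_to_crpc)
  a_cspc_pca <- .probability_array(models$cspc_to_pca_death)
  a_crpc_pca <- .probability_array(models$crpc_to_pca_death)
  oc <- .hazard_matrix(other_cause)

  npop <- nrow(population)
  ind <- rep(seq_len(npop), each = reps)
  rep_id <- rep(seq_len(reps), npop)
  n <- length(ind)

  U <- .substream_uniforms(config$seed, population$patient_id[ind], rep_id,
                           horizon + 1L)
  u_cat <- U[, horizon + 1L]

  state <- ifelse(population$start_state[ind] == "CRPC", 2L, 1L)
  cat_now <- as.integer(population$risk_category[ind])
  age0 <- population$age_years[ind]
  cci_idx <- match(population$cci, .CCI_LEVELS)[ind]
  tis <- integer(n)

  # strata: start state x start category
  strat_key <- paste(population$start_state, population$risk_category)
  strat_lv <- unique(strat_key)
  strat_idx <- match(strat_key, strat_lv)[ind]
  ns <- length(strat_lv)

  occ <- array(0L, dim = c(ns, 4L, horizon))
  evt <- array(0L, dim = c(ns, 3L, horizon))  # to_CRPC, pca_death, other_death
  traj <- if (keep_trajectories) matrix(0L, n, horizon) else NULL

  tis_band_idx <- function(tis) {
    m <- tis * .PERIOD_DAYS / .DAYS_PER_MONTH
    1L + (m >= 6) + (m >= 12) + (m >= 24) + (m >= 60)
  }
  age_band_idx <- function(age) {
    f <- floor(age)
    1L + (f >= 66) + (f >= 76) + (f >= 86)
  }

  for (t in seq_len(horizon) - 1L) {
    for (s in 1:4) {
      w <- strat_idx[state == s]
      if (length(w) > 0) occ[, s, t + 1L] <- occ[, s, t + 1L] +
          tabulate(w, nbins = ns)
    }
    if (keep_trajectories) traj[, t + 1L] <- state
    alive <- state <= 2L
    if (!any(alive)) next
    w <- which(alive)
    ab <- age_band_idx(age0[w] + t * .PERIOD_DAYS / .DAYS_PER_YEAR)
    tb <- tis_band_idx(tis[w])
    ci <- cci_idx[w]
    is_cspc <- state[w] == 1L
    look <- cbind(cat_now[w], ab, ci, tb)
    p1 <- ifelse(is_cspc, a_crpc[look], 0)          # -> CRPC
    p2 <- ifelse(is_cspc, a_cspc_pca[look], a_crpc_pca[look])  # -> PCa death
    p3 <- oc[cbind(ab, ci)]                          # -> other death
    tot <- p1 + p2 + p3
    over <- tot > 1
    if (any(over)) {
      if (config$probability_overflow_policy == "error") {
        .crpc_error("crpcstates_probability_overflow",
                    sprintf("cause-specific probabilities sum to %.3f > 1 in period %d",
                            max(tot), t))
      }
      p1[over] <- p1[over] / tot[over]
      p2[over] <- p2[over] / tot[over]
      p3[over] <- p3[over] / tot[over]
    }
    u <- U[w, t + 1L]
    go_crpc <- u < p1
    go_pca <- !go_crpc & u < p1 + p2
    go_oth <- !go_crpc & !go_pca & u < p1 + p2 + p3
    stay <- !(go_crpc | go_pca | go_oth)

    if (any(go_crpc)) {
      rows <- w[go_crpc]
      evt[, 1L, t + 1L] <- evt[, 1L, t + 1L] + tabulate(strat_idx[rows], nbins = ns)
      cat_now[rows] <- .draw_crpc_category(crpc_category_policy, cat_now[rows],
                                           u_cat[rows])
      state[rows] <- 2L
      tis[rows] <- 0L
    }
    if (any(go_pca)) {
      rows <- w[go_pca]
      evt[, 2L, t + 1L] <- evt[, 2L, t + 1L] + tabulate(strat_idx[rows], nbins = ns)
      state[rows] <- 3L
    }
    if (any(go_oth)) {
      rows <- w[go_oth]
      evt[, 3L, t + 1L] <- evt[, 3L, t + 1L] + tabulate(strat_idx[rows], nbins = ns)
      state[rows] <- 4L
    }
    tis[w[stay]] <- tis[w[stay]] + 1L
  }

  occ_df <- data.frame(
    start_state = rep(sub(" .*", "", strat_lv), times = 4L * horizon),
    start_category = as.integer(rep(sub(".* ", "", strat_lv), times = 4L * horizon)),
    state = rep(rep(.STATES, each = ns), times = horizon),
    period = rep(seq_len(horizon) - 1L, each = ns * 4L),
    count = as.integer(occ))
  evt_df <- data.frame(
    start_state = rep(sub(" .*", "", strat_lv), times = 3L * horizon),
    start_category = as.integer(rep(sub(".* ", "", strat_lv), times = 3L * horizon)),
    event = rep(rep(c("to_CRPC", "pca_death", "other_death"), each = ns),
                times = horizon),
    period = rep(seq_len(horizon) - 1L, each = ns * 3L),
    count = as.integer(evt))
  strata <- data.frame(start_state = sub(" .*", "", strat_lv),
                       start_category = as.integer(sub(".* ", "", strat_lv)),
                       n_individuals = as.integer(table(factor(strat_key,
                                                               levels = strat_lv))))
  out <- structure(list(occupancy = occ_df, events = evt_df, strata = strata,
                        replicates = reps, horizon = horizon,
                        seed = config$seed),
                   class = "occupancy_summary")
  if (keep_trajectories) {
    attr(out, "trajectories") <- traj
    attr(out, "trajectory_keys") <- data.frame(
      patient_id = population$patient_id[ind], replicate = rep_id)
  }
  out
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf("<occupancy_summary> %d strata, %d individuals x %d replicates, %d periods\n",
              nrow(x$strata), sum(x$strata$n_individuals), x$replicates, x$horizon))
  invisible(x)
}

#' Simulate one man's replicate trajectories
#'
#' Thin wrapper around [run_microsimulation()] for a single man,
#' returning the state occupied at the start of every period for each
#' replicate.
#'
#' @param models,other_cause,config,crpc_category_policy as in
#'   [run_microsimulation()].
#' @param start_state `"CSPC"` or `"CRPC"`.
#' @param covariates list with `patient_id`, `risk_category`,
#'   `age_years`, `cci`.
#' @return integer matrix (replicates x periods) of state codes
#'   (1 = CSPC, 2 = CRPC, 3 = PCa death, 4 = other death), with the
#'   state labels as attribute `states`.
#' @export
simulate_individual <- function(models, other_cause, start_state, covariates,
                                config = simulation_config(),
                                crpc_category_policy = NULL) {
  pop <- data.frame(patient_id = covariates$patient_id %||% "individual",
                    start_state = start_state,
                    risk_category = covariates$risk_category,
                    age_years = covariates$age_years,
                    cci = covariates$cci, stringsAsFactors = FALSE)
  occ <- run_microsimulation(pop, models, other_cause, config,
                             crpc_category_policy, keep_trajectories = TRUE)
  traj <- attr(occ, "trajectories")
  attr(traj, "states") <- .STATES
  traj
}

# Sum event/occupancy counts over the selected strata.
.filter_strata <- function(df, strata, start_state = NULL, start_category = NULL) {
  keep_s <- strata
  if (!is.null(start_state)) keep_s <- keep_s[keep_s$start_state %in% start_state, ]
  if (!is.null(start_category))
    keep_s <- keep_s[keep_s$start_category %in% start_category, ]
  key <- paste(df$start_state, df$start_category)
  df[key %in% paste(keep_s$start_state, keep_s$start_category), , drop = FALSE]
}

#' Predicted cumulative incidence from an occupancy summary
#'
#' `CIF(t)` = cumulative incident events of the given type through
#' period `t`, divided by (number of men in the selected strata x
#' replicates). Non-decreasing by construction; mutually exclusive event
#' CIFs plus survivors sum to 1.
#'
#' @param occupancy an `occupancy_summary`.
#' @param event `"to_CRPC"`, `"pca_death"` or `"other_death"`.
#' @param start_state,start_category optional stratum filters.
#' @return data.frame `period`, `time_days` (end of period,
#'   `(period + 1) * 28`), `cif`, with attribute `n` = denominator.
#' @export
predicted_cumulative_incidence <- function(occupancy, event,
                                           start_state = NULL,
                                           start_category = NULL) {
  if (!event %in% c("to_CRPC", "pca_death", "other_death")) {
    .crpc_error("crpcstates_bad_input", sprintf("unknown event type '%s'", event))
  }
  ev <- .filter_strata(occupancy$events, occupancy$strata, start_state,
                       start_category)
  st <- .filter_strata(occupancy$strata, occupancy$strata, start_state,
                       start_category)
  denom <- sum(st$n_individuals) * occupancy$replicates
  if (denom == 0) .crpc_error("crpcstates_no_data", "no individuals in selected strata")
  ev <- ev[ev$event == event, , drop = FALSE]
  counts <- tapply(ev$count, ev$period, sum)
  periods <- as.integer(names(counts))
  ord <- order(periods)
  cif <- cumsum(counts[ord]) / denom
  out <- data.frame(period = periods[ord],
                    time_days = (periods[ord] + 1L) * .PERIOD_DAYS,
                    cif = as.numeric(cif))
  attr(out, "n") <- denom
  out
}

#' Restricted mean time in a state
#'
#' Expected years spent in `state` within the first `horizon_periods`
#' periods: the sum over periods of the fraction of the simulated
#' population occupying the state at the period start, times 28/365.25.
#'
#' @param occupancy an `occupancy_summary`.
#' @param state one of `"CSPC"`, `"CRPC"`, `"PCaDeath"`, `"OtherDeath"`.
#' @param horizon_periods horizon (default: the summary's horizon).
#' @param start_state,start_category optional stratum filters.
#' @return years (scalar).
#' @export
restricted_mean_time_in_state <- function(occupancy, state,
                                          horizon_periods = occupancy$horizon,
                                          start_state = NULL,
                                          start_category = NULL) {
  stopifnot(state %in% .STATES, horizon_periods <= occupancy$horizon)
  oc <- .filter_strata(occupancy$occupancy, occupancy$strata, start_state,
                       start_category)
  st <- .filter_strata(occupancy$strata, occupancy$strata, start_state,
                       start_category)
  denom <- sum(st$n_individuals) * occupancy$replicates
  if (denom == 0) .crpc_error("crpcstates_no_data", "no individuals in selected strata")
  oc <- oc[oc$state == state & oc$period < horizon_periods, , drop = FALSE]
  sum(oc$count) / denom * .PERIOD_DAYS / .DAYS_PER_YEAR
}
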