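# Validation: observed competing-risks cumulative incidence
# (Aalen-Johansen via the survival package), observed-vs-predicted curve
# comparison, the end-to-end pipeline fit, two-cohort cross-validation,
# and per-category outcome summaries.

#' Observed cumulative incidence under competing risks
#'
#' Aalen-Johansen estimator of the event-type-specific cumulative
#' incidence of leaving `origin_state`, computed on the exact-day scale
#' from the state intervals: `CIF_k(t) = sum_{s<=t} S(s-) d_k(s)/n(s)`
#' with `S` the all-event Kaplan-Meier. Computed with
#' `survival::survfit` on a multi-state outcome.
#'
#' Two scopes are available. `"state_exit"` (default) treats the ways of
#' leaving `origin_state` as the competing events — for CSPC these are
#' progression to CRPC, PCa death and other-cause death. `"from_entry"`
#' follows each man from his entry into `origin_state` to his terminal
#' event across all subsequent states, so the PCa-death curve counts
#' deaths occurring after an intermediate CRPC transition too; this is
#' the estimand a whole-trajectory microsimulation predicts.
#'
#' @param intervals result of [build_state_intervals()].
#' @param origin_state `"CSPC"` or `"CRPC"`.
#' @param groups optional named vector (patient_id -> group label) to
#'   stratify the curves.
#' @param scope `"state_exit"` or `"from_entry"` (see above).
#' @return data.frame of class `cif_curves`: `group`, `event`,
#'   `time_days` (since state entry), `cif`, `n_risk`.
#' @export
observed_cumulative_incidence <- function(intervals, origin_state = "CSPC",
                                          groups = NULL,
                                          scope = c("state_exit", "from_entry")) {
  scope <- match.arg(scope)
  sub <- intervals[intervals$state == origin_state, , drop = FALSE]
  if (nrow(sub) == 0) .crpc_error("crpcstates_no_data",
                                  sprintf("no intervals in state %s", origin_state))
  if (scope == "from_entry") {
    last <- intervals[intervals$exit_reason != "to_CRPC", , drop = FALSE]
    m <- match(sub$patient_id, last$patient_id)
    time <- last$exit_day[m] - sub$entry_day
    reason <- last$exit_reason[m]
  } else {
    time <- sub$exit_day - sub$entry_day
    reason <- sub$exit_reason
  }
  ev_levels <- setdiff(.EXIT_REASONS, "censored")
  status <- factor(ifelse(reason == "censored", "censored", reason),
                   levels = c("censored", ev_levels))
  grp <- if (is.null(groups)) rep("all", nrow(sub)) else
    as.character(groups[sub$patient_id])
  if (anyNA(grp)) .crpc_error("crpcstates_bad_input",
                              "groups must cover every patient in the intervals")
  out <- list()
  for (g in unique(grp)) {
    w <- grp == g
    if (!any(w)) next
    if (all(status[w] == "censored")) {
      tt <- sort(unique(time[w]))
      for (ev in ev_levels) {
        out[[length(out) + 1]] <- data.frame(
          group = g, event = ev, time_days = tt, cif = 0,
          n_risk = vapply(tt, function(x) sum(time[w] >= x), numeric(1)))
      }
      next
    }
    fit <- survival::survfit(survival::Surv(time[w], status[w]) ~ 1)
    ps <- fit$pstate
    cols <- fit$states
    for (ev in ev_levels) {
      j <- match(ev, cols)
      if (is.na(j)) {
        cif <- rep(0, length(fit$time))
      } else {
        cif <- ps[, j]
      }
      out[[length(out) + 1]] <- data.frame(group = g, event = ev,
                                           time_days = fit$time, cif = cif,
                                           n_risk = fit$n.risk[, 1])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cif_curves", "data.frame")
  res
}

# Step interpolation of a predicted (period-grid) curve at arbitrary
# day times: value at day d is the CIF of the last completed period.
.step_interp <- function(time, value, at) {
  if (length(time) == 0) return(rep(0, length(at)))
  stats::approx(x = time, y = value, xout = at, method = "constant",
                f = 0, yleft = 0, rule = 2)$y
}

#' Compare an observed with a predicted cumulative incidence curve
#'
#' The predicted (28-day grid) curve is step-interpolated onto the
#' observed event times; reported differences are predicted minus
#' observed, so a negative value means the model under-predicts.
#'
#' @param observed data.frame with `time_days`, `cif` (one curve).
#' @param predicted data.frame with `time_days`, `cif` (one curve).
#' @param horizons_years fixed horizons at which to report differences
#'   (default 2, 5, 10 years).
#' @return one-row data.frame: `max_abs_diff`, then one `diff_<h>yr`
#'   column per horizon (predicted - observed).
#' @export
compare_curves <- function(observed, predicted, horizons_years = c(2, 5, 10)) {
  at <- observed$time_days
  pred_at <- .step_interp(predicted$time_days, predicted$cif, at)
  obs_at <- observed$cif
  out <- data.frame(max_abs_diff = if (length(at) == 0) 0 else
    max(abs(pred_at - obs_at)))
  for (h in horizons_years) {
    hd <- h * .DAYS_PER_YEAR
    p <- .step_interp(predicted$time_days, predicted$cif, hd)
    o <- .step_interp(observed$time_days, observed$cif, hd)
    out[[sprintf("diff_%gyr", h)]] <- p - o
  }
  out
}

#' Fit the full state-transition pipeline on one cohort
#'
#' Runs every stage on the training data: state construction, risk-
#' category cut points (octiles of the training values), category
#' assignment, person-period expansion, the three logistic transition
#' models, the other-cause hazard table, and the empirical conditional
#' distribution of CRPC categories given the CSPC category (used to
#' assign categories at simulated transitions). CRPC men whose doubling
#' time cannot be estimated (a single usable measurement) are
#' categorised by PSA-at-CRPC octiles instead and flagged.
#'
#' If a transition has no observed events its model is replaced by a
#' constant-zero model with a warning.
#'
#' @param cohort a validated [cohort()].
#' @param grace_days,min_adt_days,window_days state-construction
#'   parameters.
#' @param covariates covariate set for the transition models.
#' @param cutpoints optional named list (`cspc`, `crpc`) of
#'   `risk_category_spec` objects overriding the fitted octiles.
#' @param label stored in each model's training metadata.
#' @return object of class `crpc_pipeline_fit`: list with `intervals`,
#'   `categories`, `person_periods`, `cutpoints`, `models`,
#'   `other_cause`, `crpc_conditional`, `start_population`, `label`.
#' @export
fit_pipeline <- function(cohort, grace_days = 30, min_adt_days = 90,
                         window_days = 183,
                         covariates = c("risk_category", "age_band", "cci",
                                        "time_in_state_band"),
                         cutpoints = NULL, label = NA_character_) {
  intervals <- build_state_intervals(cohort, grace_days = grace_days,
                                     min_adt_days = min_adt_days,
                                     window_days = window_days)
  if (nrow(intervals) == 0) .crpc_error("crpcstates_no_data",
                                        "no patients reached the CSPC state")
  entries <- attr(intervals, "entries")
  basis <- .cspc_basis_values(cohort, entries)
  keep <- is.finite(basis)
  cut_cspc <- cutpoints$cspc %||%
    fit_category_cutpoints(basis[keep], "CSPC", "psa_level")
  cspc_cat <- rep(NA_integer_, nrow(entries))
  cspc_cat[keep] <- assign_category(basis[keep], cut_cspc)
  # men with no usable basis PSA fall into the middle category
  cspc_cat[!keep] <- 4L

  kin <- .crpc_kinetics(cohort, intervals)
  crpc_cat <- rep(NA_integer_, nrow(entries))
  cut_crpc <- NULL; cut_crpc_psa <- NULL
  if (nrow(kin) > 0) {
    ok <- !kin$missing_dt
    cut_crpc <- cutpoints$crpc %||%
      fit_category_cutpoints(kin$score[ok], "CRPC", "kinetics_score")
    m <- match(kin$patient_id, entries$patient_id)
    crpc_cat[m[ok]] <- assign_category(kin$score[ok], cut_crpc)
    if (any(kin$missing_dt)) {
      cut_crpc_psa <- fit_category_cutpoints(kin$psa_at_crpc, "CRPC", "psa_level")
      crpc_cat[m[kin$missing_dt]] <- assign_category(
        kin$psa_at_crpc[kin$missing_dt], cut_crpc_psa)
    }
  }
  categories <- data.frame(patient_id = entries$patient_id,
                           cspc_category = cspc_cat,
                           crpc_category = crpc_cat,
                           stringsAsFactors = FALSE)
  pp <- expand_person_periods(intervals, cohort$patients, categories)

  # events-per-variable safeguard: overparameterised logistic hazards on
  # small cohorts are degenerate, so the covariate set shrinks with the
  # event count (full set >= 90 events, risk category alone >= 40,
  # otherwise intercept only)
  fit_or_zero <- function(tr) {
    origin <- .TRANSITION_STATE[[tr]]
    ev <- .TRANSITIONS[[tr]]
    n_events <- sum(pp$state == origin & pp$event == ev)
    covs <- if (n_events >= 90) covariates else
      if (n_events >= 40) intersect("risk_category", covariates) else character(0)
    if (length(covs) < length(covariates)) {
      warning(sprintf("%s: only %d events; covariates reduced to {%s}", tr,
                      n_events, paste(covs, collapse = ", ")), call. = FALSE)
    }
    tryCatch(fit_transition_model(pp, tr, covariates = covs,
                                  training_label = label),
             crpcstates_no_events = function(e) {
               warning(sprintf("%s: no events; using constant-zero model", tr),
                       call. = FALSE)
               constant_transition_model(tr, 0)
             })
  }
  models <- list(cspc_to_crpc = fit_or_zero("cspc_to_crpc"),
                 cspc_to_pca_death = fit_or_zero("cspc_to_pca_death"),
                 crpc_to_pca_death = fit_or_zero("crpc_to_pca_death"))
  other_cause <- estimate_other_cause_hazard(pp)

  # empirical P(CRPC category | CSPC category), add-0.5 smoothed
  cond <- matrix(0.5, 8, 8)
  both <- categories[!is.na(categories$crpc_category), , drop = FALSE]
  if (nrow(both) > 0) {
    tab <- table(factor(both$cspc_category, levels = 1:8),
                 factor(both$crpc_category, levels = 1:8))
    cond <- unclass(tab) + 0.5
  }
  cond <- cond / rowSums(cond)

  start_pop <- .start_population(cohort, intervals, categories, "CSPC")
  structure(list(intervals = intervals, categories = categories,
                 person_periods = pp,
                 cutpoints = list(cspc = cut_cspc, crpc = cut_crpc,
                                  crpc_psa_fallback = cut_crpc_psa),
                 models = models, other_cause = other_cause,
                 crpc_conditional = cond, start_population = start_pop,
                 label = label),
            class = "crpc_pipeline_fit")
}

# Starting population for simulation: every man at his entry into
# `origin_state`, with age at entry, CCI and the state's risk category.
.start_population <- function(cohort, intervals, categories, origin_state) {
  sub <- intervals[intervals$state == origin_state, , drop = FALSE]
  m <- match(sub$patient_id, cohort$patients$patient_id)
  cm <- match(sub$patient_id, categories$patient_id)
  cat_col <- if (origin_state == "CSPC") categories$cspc_category[cm] else
    categories$crpc_category[cm]
  data.frame(patient_id = sub$patient_id,
             start_state = origin_state,
             risk_category = as.integer(cat_col),
             age_years = .age_at_day(cohort$patients$birth_year[m], sub$entry_day),
             cci = cohort$patients$cci[m],
             stringsAsFactors = FALSE)
}

# Apply a fitted pipeline to a validation cohort: assign categories with
# the training cut points and simulate from CSPC entry.
.apply_pipeline <- function(fit, cohort, sim_config, grace_days = 30,
                            min_adt_days = 90, window_days = 183) {
  intervals <- build_state_intervals(cohort, grace_days = grace_days,
                                     min_adt_days = min_adt_days,
                                     window_days = window_days)
  entries <- attr(intervals, "entries")
  basis <- .cspc_basis_values(cohort, entries)
  cat_cspc <- rep(4L, nrow(entries))
  keep <- is.finite(basis)
  cat_cspc[keep] <- assign_category(basis[keep], fit$cutpoints$cspc)
  pop <- data.frame(patient_id = entries$patient_id,
                    start_state = "CSPC",
                    risk_category = cat_cspc,
                    age_years = .age_at_day(
                      cohort$patients$birth_year[match(entries$patient_id,
                                                       cohort$patients$patient_id)],
                      entries$entry_day),
                    cci = cohort$patients$cci[match(entries$patient_id,
                                                    cohort$patients$patient_id)],
                    stringsAsFactors = FALSE)
  occ <- run_microsimulation(pop, fit$models, fit$other_cause, sim_config,
                             crpc_category_policy = fit$crpc_conditional)
  list(intervals = intervals, population = pop, occupancy = occ)
}

#' Two-cohort cross-validation of the fitted model
#'
#' Splits the registry by its cohort label (A/B), fits the full pipeline
#' on each half, simulates the other half's starting population under
#' the foreign model, and compares predicted with observed cumulative
#' incidence of progression to CRPC and of PCa death from the CSPC
#' state. No information flows from the validation cohort into fitting:
#' cut points, transition models and hazard tables all come from the
#' training half.
#'
#' @param cohort a validated [cohort()] whose patients table carries the
#'   `cohort` label.
#' @param sim_config a [simulation_config()].
#' @param horizons_years horizons for the reported differences.
#' @param ... passed to [fit_pipeline()] (state-construction
#'   parameters).
#' @return data.frame of class `validation_report`: one row per
#'   (direction, event) with `n_validation`, `max_abs_diff` and the
#'   per-horizon predicted-minus-observed differences.
#' @export
cross_validate <- function(cohort, sim_config = simulation_config(),
                           horizons_years = c(2, 5, 10), ...) {
  labs <- cohort$patients$cohort
  if (!all(c("A", "B") %in% labs)) {
    .crpc_error("crpcstates_bad_input", "cohort labels must include both A and B")
  }
  halves <- lapply(c(A = "A", B = "B"), function(l) {
    ids <- cohort$patients$patient_id[labs == l]
    cohort(cohort$patients[labs == l, ],
           cohort$psa[cohort$psa$patient_id %in% ids, ],
           cohort$dispensations[cohort$dispensations$patient_id %in% ids, ],
           cohort$surgeries[cohort$surgeries$patient_id %in% ids, ],
           cohort$vitals[cohort$vitals$patient_id %in% ids, ])
  })
  out <- list()
  for (dir in list(c("A", "B"), c("B", "A"))) {
    fit <- fit_pipeline(halves[[dir[1]]], label = dir[1], ...)
    applied <- .apply_pipeline(fit, halves[[dir[2]]], sim_config, ...)
    obs_exit <- observed_cumulative_incidence(applied$intervals, "CSPC")
    obs_entry <- observed_cumulative_incidence(applied$intervals, "CSPC",
                                               scope = "from_entry")
    horizon_days <- sim_config$horizon_periods * .PERIOD_DAYS
    for (ev in c("to_CRPC", "pca_death")) {
      obs <- if (ev == "to_CRPC") obs_exit else obs_entry
      o <- obs[obs$event == ev & obs$time_days <= horizon_days, , drop = FALSE]
      p <- predicted_cumulative_incidence(applied$occupancy, ev)
      cmp <- compare_curves(o, p, horizons_years)
      out[[length(out) + 1]] <- cbind(
        data.frame(direction = paste0(dir[1], "->", dir[2]), event = ev,
                   n_validation = nrow(applied$population)),
        cmp)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("validation_report", "data.frame")
  res
}

# Restricted mean years in a state, observed: integral over [0, horizon]
# of the Kaplan-Meier of leaving the state (any exit; censoring
# respected).
.observed_rmst <- function(time, any_event, horizon_days) {
  fit <- survival::survfit(survival::Surv(time, any_event) ~ 1)
  tt <- c(0, fit$time[fit$time <= horizon_days], horizon_days)
  ss <- c(1, fit$surv[fit$time <= horizon_days])
  ss <- c(ss, ss[length(ss)])
  sum(diff(tt) * ss[-length(ss)]) / .DAYS_PER_YEAR
}

#' Time in CRPC and PCa-death proportion by CRPC risk category
#'
#' For each CRPC risk-category group: the predicted restricted mean
#' years spent in the CRPC state within the horizon and the predicted
#' PCa-death cumulative incidence at the horizon (from a simulation of
#' men starting at CRPC entry), side by side with their observed
#' counterparts (Kaplan-Meier integral for time in state;
#' Aalen-Johansen for the death CIF).
#'
#' @param occupancy an `occupancy_summary` from simulating CRPC
#'   entrants (strata with `start_state == "CRPC"`).
#' @param intervals the observed [build_state_intervals()] result.
#' @param categories the per-patient category table (as in
#'   [fit_pipeline()]'s `categories`).
#' @param category_groups list mapping group labels to category vectors;
#'   default the four merged pairs `1-2`, `3-4`, `5-6`, `7-8`.
#' @param horizon_periods horizon (default 130 periods, 10 years).
#' @return data.frame: `category_group`, `n_observed`,
#'   `predicted_time_in_crpc_yr`, `observed_time_in_crpc_yr`,
#'   `predicted_pca_death`, `observed_pca_death`.
#' @export
summarize_outcomes <- function(occupancy, intervals, categories,
                               category_groups = list("1-2" = 1:2, "3-4" = 3:4,
                                                      "5-6" = 5:6, "7-8" = 7:8),
                               horizon_periods = 130L) {
  crpc <- intervals[intervals$state == "CRPC", , drop = FALSE]
  cm <- match(crpc$patient_id, categories$patient_id)
  crpc_cat <- categories$crpc_category[cm]
  horizon_days <- horizon_periods * .PERIOD_DAYS
  out <- list()
  for (g in names(category_groups)) {
    cats <- category_groups[[g]]
    has_pred <- any(occupancy$strata$start_state == "CRPC" &
                      occupancy$strata$start_category %in% cats)
    pred_rmst <- if (has_pred)
      restricted_mean_time_in_state(occupancy, "CRPC", horizon_periods,
                                    start_state = "CRPC", start_category = cats)
    else NA_real_
    pred_cif <- if (has_pred) {
      pc <- predicted_cumulative_incidence(occupancy, "pca_death",
                                           start_state = "CRPC",
                                           start_category = cats)
      max(c(0, pc$cif[pc$period < horizon_periods]))
    } else NA_real_
    w <- which(crpc_cat %in% cats)
    obs_rmst <- obs_cif <- NA_real_
    if (length(w) > 0) {
      time <- crpc$exit_day[w] - crpc$entry_day[w]
      obs_rmst <- .observed_rmst(time, crpc$exit_reason[w] != "censored",
                                 horizon_days)
      st <- factor(ifelse(crpc$exit_reason[w] == "censored", "censored",
                          crpc$exit_reason[w]),
                   levels = c("censored", "pca_death", "other_death"))
      obs_cif <- 0
      if (any(st != "censored")) {
        fit <- survival::survfit(survival::Surv(time, st) ~ 1)
        j <- match("pca_death", fit$states)
        keep <- fit$time <= horizon_days
        obs_cif <- if (!is.na(j) && any(keep)) max(fit$pstate[keep, j]) else 0
      }
    }
    out[[length(out) + 1]] <- data.frame(
      category_group = g, n_observed = length(w),
      predicted_time_in_crpc_yr = pred_rmst,
      observed_time_in_crpc_yr = obs_rmst,
      predicted_pca_death = pred_cif,
      observed_pca_death = obs_cif)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
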