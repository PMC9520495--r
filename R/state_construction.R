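# State construction: ADT exposure, CSPC entry, PSA nadir tracking, CRPC
# detection, state intervals and 28-day person-period expansion.
#
# Entry rules: a man enters the castration-sensitive (CSPC) state once he
# has accrued 90 days of GnRH supply within a 183-day window, or on the
# date of bilateral orchidectomy. He enters the castration-resistant
# (CRPC) state at the first PSA measurement that doubles his running
# nadir with the value >2 ng/ml, or that exceeds the nadir by >=5 ng/ml,
# provided he has accrued at least 90 days of ADT exposure by then.

#' Androgen-deprivation exposure from dispensations and surgery
#'
#' Each GnRH dispensation covers `[date, date + days_supply + grace_days)`;
#' an orchidectomy covers from the surgery date onward permanently. The
#' exposure is the union of these intervals, kept as half-open integer-day
#' intervals.
#'
#' @param dispensations data.frame of one patient's dispensations
#'   (`date`, `drug_class`, `days_supply`); only GnRH rows contribute.
#' @param surgeries data.frame of the patient's surgeries
#'   (`orchidectomy_date`), at most one row.
#' @param grace_days days of assumed continued castration after a supply
#'   runs out (default 30).
#' @return object of class `adt_exposure`: list with `intervals` (matrix
#'   of half-open `[start, end)` day offsets, merged and sorted) and
#'   `orchidectomy_day` (integer day or `NA`).
#' @export
compute_adt_exposure <- function(dispensations, surgeries, grace_days = 30) {
  starts <- integer(0); ends <- numeric(0)
  if (!is.null(dispensations) && nrow(dispensations) > 0) {
    g <- dispensations[dispensations$drug_class == "GnRH", , drop = FALSE]
    if (nrow(g) > 0) {
      starts <- .day(g$date)
      ends <- starts + g$days_supply + grace_days
    }
  }
  orch_day <- NA_integer_
  if (!is.null(surgeries) && nrow(surgeries) > 0) {
    orch_day <- min(.day(surgeries$orchidectomy_date))
    starts <- c(starts, orch_day)
    ends <- c(ends, Inf)
  }
  if (length(starts) == 0) {
    return(structure(list(intervals = matrix(numeric(0), ncol = 2,
                                             dimnames = list(NULL, c("start", "end"))),
                          orchidectomy_day = orch_day), class = "adt_exposure"))
  }
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  # merge overlapping / touching intervals
  ms <- starts[1]; me <- ends[1]; out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out[[length(out) + 1]] <- c(ms, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out[[length(out) + 1]] <- c(ms, me)
  ints <- do.call(rbind, out)
  colnames(ints) <- c("start", "end")
  structure(list(intervals = ints, orchidectomy_day = orch_day),
            class = "adt_exposure")
}

# Covered days in [from, to] (inclusive integer days).
.coverage_in <- function(exposure, from, to) {
  if (to < from) return(0)
  ints <- exposure$intervals
  if (nrow(ints) == 0) return(0)
  lo <- pmax(ints[, "start"], from)
  hi <- pmin(ints[, "end"], to + 1)  # half-open
  sum(pmax(hi - lo, 0))
}

# Cumulative covered days up to and including `day`.
.coverage_through <- function(exposure, day) {
  .coverage_in(exposure, -Inf, day)
}

#' Date of entry into the castration-sensitive state
#'
#' Returns the orchidectomy day if the man was surgically castrated;
#' otherwise the earliest day `d` by which at least `required_days` (90)
#' covered days have accrued within the `window_days` (183) window ending
#' at `d`; `NA` if never satisfied.
#'
#' @param exposure an [compute_adt_exposure()] result.
#' @param window_days rolling window length in days (default 183, i.e.
#'   6 months).
#' @param required_days covered days required within the window (default
#'   90, i.e. 3 months).
#' @return integer day offset of CSPC entry, or `NA_integer_`.
#' @export
detect_cspc_entry <- function(exposure, window_days = 183, required_days = 90) {
  if (!is.na(exposure$orchidectomy_day)) return(as.integer(exposure$orchidectomy_day))
  ints <- exposure$intervals
  if (nrow(ints) == 0) return(NA_integer_)
  # daily coverage indicator over the exposed range; the first qualifying
  # day is necessarily a covered day, since the rolling count only
  # increases on covered days.
  d0 <- min(ints[, "start"]); d1 <- max(ints[, "end"])
  cov <- logical(d1 - d0)
  for (r in seq_len(nrow(ints))) {
    cov[seq(ints[r, "start"] - d0 + 1, ints[r, "end"] - d0)] <- TRUE
  }
  cs <- cumsum(cov)
  lag <- c(rep(0, min(window_days, length(cs))), cs)[seq_along(cs)]
  w <- cs - lag
  hit <- which(w >= required_days & cov)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(d0 + hit[1] - 1)
}

#' Running PSA nadir since CSPC entry
#'
#' The nadir series evaluated at each PSA date from CSPC entry onward.
#' Two minima are carried: `nadir`, the running minimum including the
#' current value, and `nadir_before`, the running minimum over strictly
#' earlier measurements (the baseline a value is compared against in the
#' CRPC rule — a measurement can never be its own nadir).
#'
#' @param psa data.frame of one patient's PSA (`date`, `value`), any
#'   order.
#' @param entry_day integer day of CSPC entry (measurements before it are
#'   ignored).
#' @return data.frame `day`, `value`, `nadir`, `nadir_before`
#'   (`nadir_before` is `NA` for the first measurement), or `NULL` when
#'   no PSA on/after entry.
#' @export
compute_nadir_series <- function(psa, entry_day) {
  d <- .day(psa$date)
  keep <- d >= entry_day
  if (!any(keep)) return(NULL)
  d <- d[keep]; v <- psa$value[keep]
  ord <- order(d)
  d <- d[ord]; v <- v[ord]
  nad <- cummin(v)
  nb <- c(NA_real_, nad[-length(nad)])
  data.frame(day = d, value = v, nadir = nad, nadir_before = nb)
}

#' Detect entry into the castration-resistant state
#'
#' Scans the nadir series for the earliest measurement satisfying either
#' progression criterion — doubling of the prior nadir with the value
#' strictly above 2 ng/ml, or an absolute increase of at least 5 ng/ml
#' over the prior nadir — subject to at least `min_adt_days` of
#' cumulative ADT exposure by that date. Whichever criterion is met
#' first triggers.
#'
#' @param nadir_series result of [compute_nadir_series()].
#' @param exposure the patient's [compute_adt_exposure()].
#' @param min_adt_days cumulative ADT coverage required at the trigger
#'   date (default 90).
#' @return list with `day` (integer) and `psa` (the triggering value),
#'   or `NULL` when never satisfied.
#' @export
detect_crpc <- function(nadir_series, exposure, min_adt_days = 90) {
  if (is.null(nadir_series) || nrow(nadir_series) < 2) return(NULL)
  for (i in seq_len(nrow(nadir_series))[-1]) {
    v <- nadir_series$value[i]
    nb <- nadir_series$nadir_before[i]
    doubling <- (v >= 2 * nb) && (v > 2)
    absolute <- (v - nb) >= 5
    if ((doubling || absolute) &&
        .coverage_through(exposure, nadir_series$day[i]) >= min_adt_days) {
      return(list(day = nadir_series$day[i], psa = v, nadir = nb))
    }
  }
  NULL
}

#' Build CSPC / CRPC state intervals for every man in a cohort
#'
#' Applies the full entry machinery per patient: ADT exposure, CSPC
#' entry, nadir tracking, CRPC detection, then truncation at death or
#' administrative censoring. Patients who never reach CSPC, or who die or
#' are censored before entry, are excluded with a logged reason.
#'
#' @param cohort a validated [cohort()].
#' @param grace_days grace period after supply exhaustion (default 30).
#' @param min_adt_days,window_days entry-rule day counts (defaults 90 and
#'   183).
#' @return data.frame with one row per patient-state: `patient_id`,
#'   `state`, `entry_day`, `exit_day`, `exit_reason` in
#'   `to_CRPC, pca_death, other_death, censored`. Attributes:
#'   `crpc_info` (per CRPC man: `crpc_day`, `psa_at_crpc`,
#'   `nadir_at_crpc`), `entries` (per included man: `entry_day`,
#'   `adt_start_day`), `excluded` (patient_id + reason).
#' @export
build_state_intervals <- function(cohort, grace_days = 30, min_adt_days = 90,
                                  window_days = 183) {
  stopifnot(inherits(cohort, "crpc_cohort"))
  ids <- cohort$patients$patient_id
  disp_split <- split(cohort$dispensations, cohort$dispensations$patient_id)
  surg_split <- split(cohort$surgeries, cohort$surgeries$patient_id)
  psa_split <- split(cohort$psa, cohort$psa$patient_id)
  vit <- cohort$vitals
  vit_idx <- match(ids, vit$patient_id)

  rows <- list(); crpc_rows <- list(); entry_rows <- list(); excl <- list()
  for (j in seq_along(ids)) {
    id <- ids[j]
    vi <- vit_idx[j]
    if (is.na(vi)) {
      excl[[length(excl) + 1]] <- data.frame(patient_id = id,
                                             reason = "no vital record")
      next
    }
    death_day <- if (is.na(vit$death_date[vi])) NA_integer_ else .day(vit$death_date[vi])
    censor_day <- .day(vit$censor_date[vi])
    cause <- vit$cause[vi]
    exposure <- compute_adt_exposure(disp_split[[id]], surg_split[[id]],
                                     grace_days = grace_days)
    entry <- detect_cspc_entry(exposure, window_days = window_days,
                               required_days = min_adt_days)
    if (is.na(entry)) {
      excl[[length(excl) + 1]] <- data.frame(patient_id = id,
                                             reason = "never reached CSPC")
      next
    }
    end_fu <- if (is.na(death_day)) censor_day else min(death_day, censor_day)
    if (end_fu <= entry) {
      excl[[length(excl) + 1]] <- data.frame(patient_id = id,
                                             reason = "follow-up ended before CSPC entry")
      next
    }
    ps <- psa_split[[id]]
    nser <- if (is.null(ps)) NULL else {
      ps2 <- ps[.day(ps$date) <= end_fu, , drop = FALSE]
      compute_nadir_series(ps2, entry)
    }
    crpc <- detect_crpc(nser, exposure, min_adt_days = min_adt_days)
    if (!is.null(crpc) && crpc$day >= end_fu) crpc <- NULL
    terminal <- if (is.na(death_day) || censor_day < death_day) "censored"
                else if (identical(cause, "PCa")) "pca_death" else "other_death"
    adt_start <- if (nrow(exposure$intervals) > 0) exposure$intervals[1, "start"]
                 else entry
    entry_rows[[length(entry_rows) + 1]] <-
      data.frame(patient_id = id, entry_day = as.integer(entry),
                 adt_start_day = as.integer(adt_start))
    if (is.null(crpc)) {
      rows[[length(rows) + 1]] <-
        data.frame(patient_id = id, state = "CSPC", entry_day = as.integer(entry),
                   exit_day = as.integer(end_fu), exit_reason = terminal)
    } else {
      rows[[length(rows) + 1]] <-
        data.frame(patient_id = id, state = "CSPC", entry_day = as.integer(entry),
                   exit_day = as.integer(crpc$day), exit_reason = "to_CRPC")
      rows[[length(rows) + 1]] <-
        data.frame(patient_id = id, state = "CRPC", entry_day = as.integer(crpc$day),
                   exit_day = as.integer(end_fu), exit_reason = terminal)
      crpc_rows[[length(crpc_rows) + 1]] <-
        data.frame(patient_id = id, crpc_day = as.integer(crpc$day),
                   psa_at_crpc = crpc$psa, nadir_at_crpc = crpc$nadir)
    }
  }
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)[0, , drop = FALSE]
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    empty(patient_id = "", state = "", entry_day = 0L, exit_day = 0L,
          exit_reason = "")
  rownames(out) <- NULL
  attr(out, "crpc_info") <- if (length(crpc_rows) > 0) do.call(rbind, crpc_rows) else
    empty(patient_id = "", crpc_day = 0L, psa_at_crpc = 0, nadir_at_crpc = 0)
  attr(out, "entries") <- if (length(entry_rows) > 0) do.call(rbind, entry_rows) else
    empty(patient_id = "", entry_day = 0L, adt_start_day = 0L)
  attr(out, "excluded") <- if (length(excl) > 0) do.call(rbind, excl) else
    empty(patient_id = "", reason = "")
  out
}

#' Expand state intervals into 28-day person-periods
#'
#' One row per man per 28-day interval at risk in a state: the unit of
#' discrete-time hazard estimation. An interval of `L` days yields
#' `ceiling(L / 28)` rows on the half-open grid `[28k, 28(k+1))` from
#' state entry; the terminal event is assigned to the period containing
#' the exit date (always the last row); the final partial period is kept
#' as a full row, with its actual residual days recorded in
#' `days_in_period` for time accounting.
#'
#' @param intervals result of [build_state_intervals()].
#' @param patients the cohort's patients table (for birth year and CCI).
#' @param categories data.frame `patient_id`, `cspc_category`,
#'   `crpc_category` (integers 1..8; `crpc_category` may be `NA` for men
#'   never reaching CRPC).
#' @return data.frame: `patient_id`, `state`, `period_index`,
#'   `days_in_period`, `age_band`, `cci`, `risk_category`,
#'   `time_in_state_band`, `event`.
#' @export
expand_person_periods <- function(intervals, patients, categories) {
  if (nrow(intervals) == 0) {
    return(data.frame(patient_id = character(0), state = character(0),
                      period_index = integer(0), days_in_period = integer(0),
                      age_band = character(0), cci = character(0),
                      risk_category = integer(0),
                      time_in_state_band = character(0), event = character(0)))
  }
  pid <- match(intervals$patient_id, patients$patient_id)
  birth_year <- patients$birth_year[pid]
  cci <- patients$cci[pid]
  cid <- match(intervals$patient_id, categories$patient_id)
  cat_cspc <- categories$cspc_category[cid]
  cat_crpc <- categories$crpc_category[cid]

  L <- intervals$exit_day - intervals$entry_day
  nper <- pmax(ceiling(L / .PERIOD_DAYS), 1L)
  idx <- rep(seq_len(nrow(intervals)), nper)
  k <- unlist(lapply(nper, function(m) seq_len(m) - 1L), use.names = FALSE)
  last <- unlist(lapply(nper, function(m) seq_len(m) == m), use.names = FALSE)

  period_start <- intervals$entry_day[idx] + .PERIOD_DAYS * k
  days_in <- ifelse(last, intervals$exit_day[idx] - period_start,
                    .PERIOD_DAYS)
  event <- ifelse(last & intervals$exit_reason[idx] != "censored",
                  intervals$exit_reason[idx], "none")
  age <- .age_at_day(birth_year[idx], period_start)
  months_in_state <- (.PERIOD_DAYS * k) / .DAYS_PER_MONTH
  risk_cat <- ifelse(intervals$state[idx] == "CSPC", cat_cspc[idx], cat_crpc[idx])

  data.frame(patient_id = intervals$patient_id[idx],
             state = intervals$state[idx],
             period_index = as.integer(k),
             days_in_period = as.integer(days_in),
             age_band = as.character(age_band(age)),
             cci = cci[idx],
             risk_category = as.integer(risk_cat),
             time_in_state_band = as.character(time_in_state_band(months_in_state)),
             event = event,
             stringsAsFactors = FALSE)
}
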