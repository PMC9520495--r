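# PSA kinetics risk scoring: doubling time, the combined kinetics score
# log(PSA at CRPC) - 1.4 * log(PSADT), and the eight-level risk
# categories for both castration states.

.PSADT_CLAMP <- c(0.01, 10)

#' PSA doubling time by log-linear least squares
#'
#' Slope of `ln(PSA)` on time in years over the window from the nadir
#' date through the CRPC date (inclusive); doubling time is
#' `ln(2) / slope`. A non-positive slope is clamped to the upper bound;
#' the result is clamped to `clamp` (default `[0.01, 10]` years) so
#' near-flat or noisy series cannot dominate the kinetics score.
#'
#' @param days integer day offsets of the measurements.
#' @param values PSA values in ng/ml.
#' @param clamp lower/upper clamp in years.
#' @return doubling time in years.
#' @export
psa_doubling_time <- function(days, values, clamp = .PSADT_CLAMP) {
  keep <- is.finite(days) & is.finite(values) & values > 0
  days <- days[keep]; values <- values[keep]
  if (length(unique(days)) < 2) {
    .crpc_error("crpcstates_insufficient_psa",
                "insufficient PSA for DT: need >= 2 measurements with distinct dates")
  }
  t_years <- days / .DAYS_PER_YEAR
  beta <- stats::cov(t_years, log(values)) / stats::var(t_years)
  dt <- if (beta <= 0) clamp[2] else log(2) / beta
  min(max(dt, clamp[1]), clamp[2])
}

#' Combined PSA kinetics risk score
#'
#' `ln(psa_at_crpc) - 1.4 * ln(psadt)`: higher PSA at the transition to
#' castration resistance and a shorter doubling time both raise the
#' score. The 1.4 weight is taken as fixed from the published kinetics
#' model; natural logarithms are used throughout.
#'
#' @param psa_at_crpc PSA at CRPC in ng/ml (positive).
#' @param psadt PSA doubling time in years (positive, pre-clamped).
#' @return dimensionless score (vectorised).
#' @export
combined_kinetics_risk <- function(psa_at_crpc, psadt) {
  if (any(!is.finite(psa_at_crpc) | psa_at_crpc <= 0) ||
      any(!is.finite(psadt) | psadt <= 0)) {
    .crpc_error("crpcstates_bad_input",
                "psa_at_crpc and psadt must be positive and finite")
  }
  log(psa_at_crpc) - 1.4 * log(psadt)
}

#' Fit eight-level risk-category cut points
#'
#' Cut points at the seven octile boundaries (quantiles 1/8 .. 7/8) of
#' the training values. The exact category boundaries used with the
#' register data are not publicly available, so octiles of the training
#' cohort are the default; externally supplied cut points can be wrapped
#' with `risk_category_spec()`.
#'
#' @param values training values (PSA levels for CSPC, kinetics scores
#'   for CRPC); at least 8 finite values.
#' @param state `"CSPC"` or `"CRPC"`.
#' @param basis `"psa_level"` or `"kinetics_score"`.
#' @return object of class `risk_category_spec`.
#' @export
fit_category_cutpoints <- function(values, state = c("CSPC", "CRPC"),
                                   basis = c("psa_level", "kinetics_score")) {
  state <- match.arg(state); basis <- match.arg(basis)
  values <- values[is.finite(values)]
  if (length(values) < 8) {
    .crpc_error("crpcstates_too_few_values",
                "need >= 8 finite values to fit octile cut points")
  }
  if (max(values) == min(values)) {
    .crpc_error("crpcstates_degenerate",
                "degenerate distribution: all training values equal")
  }
  cuts <- unname(stats::quantile(values, probs = (1:7) / 8, type = 7))
  risk_category_spec(cuts, state = state, basis = basis,
                     provenance = "fitted_octiles")
}

#' @rdname fit_category_cutpoints
#' @param cutpoints seven strictly ascending thresholds.
#' @param provenance `"fitted_octiles"` or `"user_supplied"`.
#' @export
risk_category_spec <- function(cutpoints, state = c("CSPC", "CRPC"),
                               basis = c("psa_level", "kinetics_score"),
                               provenance = "user_supplied") {
  state <- match.arg(state); basis <- match.arg(basis)
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) != 7 || any(!is.finite(cutpoints)) ||
      any(diff(cutpoints) <= 0)) {
    .crpc_error("crpcstates_bad_cutpoints",
                "cutpoints must be 7 strictly ascending finite thresholds")
  }
  structure(list(state = state, basis = basis, cutpoints = cutpoints,
                 provenance = provenance), class = "risk_category_spec")
}

#' Assign an eight-level risk category
#'
#' Category `k` iff the value lies in `(cut[k-1], cut[k]]` (right-closed:
#' a value exactly at a cut point takes the lower category); below the
#' first cut gives 1, above the last gives 8. Monotone non-decreasing in
#' the value.
#'
#' @param value numeric vector to categorise.
#' @param spec a `risk_category_spec`.
#' @return integer vector of categories 1..8.
#' @export
assign_category <- function(value, spec) {
  stopifnot(inherits(spec, "risk_category_spec"))
  if (any(!is.finite(value))) {
    .crpc_error("crpcstates_bad_input", "values to categorise must be finite")
  }
  1L + rowSums(outer(value, spec$cutpoints, `>`))
}

# Basis value for CSPC categorisation: the last PSA within `window` days
# after ADT initiation (first GnRH dispensation or orchidectomy); falls
# back to the closest PSA before ADT start when none exists in-window.
.cspc_basis_values <- function(cohort, entries, window = 90) {
  psa_split <- split(cohort$psa, cohort$psa$patient_id)
  vapply(seq_len(nrow(entries)), function(i) {
    ps <- psa_split[[entries$patient_id[i]]]
    if (is.null(ps)) return(NA_real_)
    d <- .day(ps$date); v <- ps$value
    a <- entries$adt_start_day[i]
    inwin <- d >= a & d <= a + window
    if (any(inwin)) return(v[inwin][which.max(d[inwin])])
    before <- d < a
    if (any(before)) return(v[before][which.max(d[before])])
    NA_real_
  }, numeric(1))
}

# Kinetics quantities for every man reaching CRPC: PSA at CRPC, PSADT
# over the window from the date the final pre-CRPC nadir was attained
# through the CRPC date (inclusive), and the combined score. Men with a
# single usable measurement get NA psadt (flagged); their category falls
# back to PSA-at-CRPC octiles.
.crpc_kinetics <- function(cohort, intervals) {
  info <- attr(intervals, "crpc_info")
  entries <- attr(intervals, "entries")
  if (nrow(info) == 0) {
    return(data.frame(patient_id = character(0), psa_at_crpc = numeric(0),
                      psadt = numeric(0), score = numeric(0),
                      missing_dt = logical(0)))
  }
  psa_split <- split(cohort$psa, cohort$psa$patient_id)
  out <- lapply(seq_len(nrow(info)), function(i) {
    id <- info$patient_id[i]
    entry <- entries$entry_day[match(id, entries$patient_id)]
    ps <- psa_split[[id]]
    d <- .day(ps$date); v <- ps$value
    keep <- d >= entry & d <= info$crpc_day[i]
    d <- d[keep]; v <- v[keep]
    ord <- order(d); d <- d[ord]; v <- v[ord]
    # date the final pre-trigger nadir was attained
    pre <- seq_len(length(d) - 1)
    nadir_idx <- pre[which.min(v[pre])]
    wd <- d[nadir_idx:length(d)]; wv <- v[nadir_idx:length(d)]
    psadt <- if (length(unique(wd)) >= 2) psa_doubling_time(wd, wv) else NA_real_
    score <- if (is.na(psadt)) NA_real_ else
      combined_kinetics_risk(info$psa_at_crpc[i], psadt)
    data.frame(patient_id = id, psa_at_crpc = info$psa_at_crpc[i],
               psadt = psadt, score = score, missing_dt = is.na(psadt))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Serialize / read risk-category cut points
#'
#' JSON round trip of a `risk_category_spec` (state, basis, the seven
#' thresholds, provenance). Requires the jsonlite package.
#'
#' @param spec a `risk_category_spec`.
#' @param path JSON file path.
#' @return `write_cutpoints()`: invisibly `path`; `read_cutpoints()`: the
#'   spec.
#' @export
write_cutpoints <- function(spec, path) {
  stopifnot(inherits(spec, "risk_category_spec"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    .crpc_error("crpcstates_missing_dep", "jsonlite is required for JSON I/O")
  }
  jsonlite::write_json(list(state = spec$state, basis = spec$basis,
                            cutpoints = spec$cutpoints,
                            provenance = spec$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cutpoints
#' @export
read_cutpoints <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    .crpc_error("crpcstates_missing_dep", "jsonlite is required for JSON I/O")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_category_spec(x$cutpoints, state = x$state, basis = x$basis,
                     provenance = x$provenance)
}
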