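# Shared constants, small helpers and error conditions.

.STATES <- c("CSPC", "CRPC", "PCaDeath", "OtherDeath")
.EXIT_REASONS <- c("to_CRPC", "pca_death", "other_death", "censored")
.EVENTS <- c("none", "to_CRPC", "pca_death", "other_death")
.AGE_BANDS <- c("<=65", "66-75", "76-85", ">=86")
.CCI_LEVELS <- c("0", "1", "2", "3+")
.TIS_BANDS <- c("0-6", "6-12", "12-24", "24-60", "60+")
.DRUG_CLASSES <- c("GnRH", "antiandrogen")
.CAUSES <- c("PCa", "other")
.PERIOD_DAYS <- 28L
.DAYS_PER_YEAR <- 365.25
.DAYS_PER_MONTH <- 30.4375

`%||%` <- function(a, b) if (is.null(a)) b else a

.crpc_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "crpcstates_error", "error")))
}

#' Age band used throughout the state transition model
#'
#' Ages are grouped into the four bands used to stratify both the hazard
#' models and the other-cause mortality table: `<=65`, `66-75`, `76-85`,
#' `>=86` years. Fractional ages are floored before banding.
#'
#' @param age numeric vector of ages in years.
#' @return factor with the four band levels.
#' @export
age_band <- function(age) {
  f <- floor(age)
  idx <- 1L + (f >= 66) + (f >= 76) + (f >= 86)
  factor(.AGE_BANDS[idx], levels = .AGE_BANDS)
}

#' Time-in-state band
#'
#' Elapsed time in the current disease state, in months, grouped into the
#' five bands used as a categorical covariate in the period hazard models:
#' `[0,6)`, `[6,12)`, `[12,24)`, `[24,60)`, `[60,Inf)` months.
#'
#' @param months numeric vector of elapsed months since state entry.
#' @return factor with the five band levels.
#' @export
time_in_state_band <- function(months) {
  idx <- 1L + (months >= 6) + (months >= 12) + (months >= 24) + (months >= 60)
  factor(.TIS_BANDS[idx], levels = .TIS_BANDS)
}

# Integer day offset for a Date (days since 1970-01-01); all internal
# arithmetic is on integer days so the 28-day grid is exact.
.day <- function(date) as.integer(as.numeric(date))

# Mid-year reference date for a birth year; with only the birth year
# recorded, age is computed against July 1 of that year.
.age_at_day <- function(birth_year, day) {
  origin <- .day(as.Date(paste0(birth_year, "-07-01")))
  (day - origin) / .DAYS_PER_YEAR
}

# Deterministic 31-bit polynomial hash of a string, for RNG substreams.
.hash_string <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Per-(id, replicate) uniform streams keyed on the master seed. Each row of
# the returned matrix is generated from its own seed, so results do not
# depend on the order or partitioning of individuals.
.substream_uniforms <- function(master_seed, ids, reps, n) {
  m <- 2147483647
  idh <- .hash_string(as.character(ids))
  seeds <- (idh * 69069 + as.numeric(reps) * 1234567 +
              (as.numeric(master_seed) %% m) * 40503) %% m
  out <- matrix(0, nrow = length(seeds), ncol = n)
  for (i in seq_along(seeds)) {
    set.seed(seeds[i])
    out[i, ] <- stats::runif(n)
  }
  out
}
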