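# Synthetic registry generator.
#
# Emulates the structure of the Swedish PSA-register linkages the model
# was built on: per-man PSA trajectories that decline to a nadir under
# androgen deprivation and then rise exponentially, monthly GnRH
# dispensing episodes with occasional gaps, occasional orchidectomy,
# cause-specific deaths on the 28-day grid, and a two-cohort (A/B) split
# for cross-validation. Every man carries known ground truth so the
# downstream state rules, kinetics estimators and hazard fits can be
# tested for recovery.

#' Configuration for the synthetic registry generator
#'
#' Defaults describe a plausible advanced-prostate-cancer ADT cohort:
#' PSA at ADT start log-normal around 30 ng/ml; a deep response to a
#' nadir around 5% of baseline with a ~30-day decline half-life; a
#' post-nadir PSA doubling time log-normal around 0.7 years; PSA
#' measured roughly every two months with 10% multiplicative noise; age
#' mix and comorbidity drawn to match the published register cohort
#' composition (see [swedish_registry_reference()]); 10 years of
#' follow-up.
#'
#' @param n_patients number of men to simulate.
#' @param cohort_split fraction assigned to cohort A (the rest to B).
#' @param seed integer seed; identical configs generate identical cohorts.
#' @param baseline_psa_log_mean,baseline_psa_log_sd log-scale mean/sd of
#'   PSA at ADT start (ng/ml).
#' @param nadir_fraction_log_mean,nadir_fraction_log_sd log-scale
#'   mean/sd of the nadir/baseline fraction (truncated below 0.9).
#' @param decline_halflife_days half-life of the PSA decline under ADT.
#' @param doubling_time_log_mean,doubling_time_log_sd log-scale mean/sd
#'   of the post-nadir PSA doubling time (years).
#' @param psa_noise_cv coefficient of variation of multiplicative
#'   log-normal measurement noise.
#' @param psa_sampling_interval_days mean gap between PSA tests.
#' @param base_pca_death_logit,risk_coefficient per-28-day logit of PCa
#'   death in the CRPC state: `plogis(base + coef * true_risk_score)`.
#' @param cspc_pca_death_prob constant per-28-day PCa-death probability
#'   in the CSPC state.
#' @param other_cause_prob_by_age named vector of per-28-day other-cause
#'   death probabilities for the four age bands.
#' @param orchidectomy_fraction probability of surgical castration
#'   instead of GnRH dispensing.
#' @param dispensation_gap_prob probability of a one-month gap after a
#'   supply runs out.
#' @param followup_years administrative censoring horizon.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 500,
                             cohort_split = 0.5,
                             seed = 1L,
                             baseline_psa_log_mean = log(30),
                             baseline_psa_log_sd = 0.9,
                             nadir_fraction_log_mean = log(0.05),
                             nadir_fraction_log_sd = 0.8,
                             decline_halflife_days = 30,
                             doubling_time_log_mean = log(0.7),
                             doubling_time_log_sd = 0.6,
                             psa_noise_cv = 0.1,
                             psa_sampling_interval_days = 60,
                             base_pca_death_logit = -4.5,
                             risk_coefficient = 0.35,
                             cspc_pca_death_prob = 0.001,
                             other_cause_prob_by_age = c("<=65" = 5e-4,
                                                         "66-75" = 1.5e-3,
                                                         "76-85" = 4e-3,
                                                         ">=86" = 0.01),
                             orchidectomy_fraction = 0.05,
                             dispensation_gap_prob = 0.05,
                             followup_years = 10) {
  cfg <- list(n_patients = as.integer(n_patients), cohort_split = cohort_split,
              seed = as.integer(seed),
              baseline_psa_log_mean = baseline_psa_log_mean,
              baseline_psa_log_sd = baseline_psa_log_sd,
              nadir_fraction_log_mean = nadir_fraction_log_mean,
              nadir_fraction_log_sd = nadir_fraction_log_sd,
              decline_halflife_days = decline_halflife_days,
              doubling_time_log_mean = doubling_time_log_mean,
              doubling_time_log_sd = doubling_time_log_sd,
              psa_noise_cv = psa_noise_cv,
              psa_sampling_interval_days = psa_sampling_interval_days,
              base_pca_death_logit = base_pca_death_logit,
              risk_coefficient = risk_coefficient,
              cspc_pca_death_prob = cspc_pca_death_prob,
              other_cause_prob_by_age = other_cause_prob_by_age,
              orchidectomy_fraction = orchidectomy_fraction,
              dispensation_gap_prob = dispensation_gap_prob,
              followup_years = followup_years)
  if (cfg$n_patients <= 0) .crpc_error("crpcstates_bad_config", "n_patients must be positive")
  if (cfg$cohort_split <= 0 || cfg$cohort_split >= 1)
    .crpc_error("crpcstates_bad_config", "cohort_split must be in (0, 1)")
  probs <- c(cfg$cspc_pca_death_prob, cfg$other_cause_prob_by_age,
             cfg$orchidectomy_fraction, cfg$dispensation_gap_prob)
  if (any(probs < 0 | probs > 1))
    .crpc_error("crpcstates_bad_config", "all probabilities must lie in [0, 1]")
  if (any(c(cfg$decline_halflife_days, cfg$psa_sampling_interval_days) <= 0))
    .crpc_error("crpcstates_bad_config", "scale parameters must be positive")
  if (!all(.AGE_BANDS %in% names(cfg$other_cause_prob_by_age)))
    .crpc_error("crpcstates_bad_config",
                "other_cause_prob_by_age must name all four age bands")
  structure(cfg, class = "generator_config")
}

# Day (since ADT start) at which the declining branch is within 1% of the
# nadir; the trajectory switches to exponential rise there.
.nadir_day <- function(baseline, nadir, halflife) {
  halflife * log2((baseline - nadir) / (0.01 * nadir))
}

#' Noiseless PSA trajectory under ADT
#'
#' Exponential decline from baseline to nadir followed by exponential
#' rise: for `t <= t_nadir`,
#' `nadir + (baseline - nadir) * 2^(-t / halflife)`; afterwards
#' `nadir * 2^((t - t_nadir) / DT_days)` with
#' `DT_days = doubling_time_years * 365.25`. `t_nadir` is the day the
#' declining branch comes within 1% of the nadir. The shape is the
#' minimal one consistent with the nadir/doubling-time constructs of the
#' CRPC progression rule, and gives the rule a closed-form crossing time.
#'
#' @param t days since ADT start (vectorised, non-negative).
#' @param baseline PSA at ADT start, ng/ml.
#' @param nadir nadir PSA, ng/ml (`< baseline`).
#' @param doubling_time_years post-nadir PSA doubling time in years.
#' @param decline_halflife_days half-life of the decline phase.
#' @return PSA in ng/ml at each `t`.
#' @export
psa_trajectory_value <- function(t, baseline, nadir, doubling_time_years,
                                 decline_halflife_days = 30) {
  if (any(t < 0)) .crpc_error("crpcstates_bad_input", "t must be non-negative")
  stopifnot(nadir > 0, baseline > nadir, doubling_time_years > 0)
  t_nadir <- .nadir_day(baseline, nadir, decline_halflife_days)
  dt_days <- doubling_time_years * .DAYS_PER_YEAR
  ifelse(t <= t_nadir,
         nadir + (baseline - nadir) * 2^(-t / decline_halflife_days),
         nadir * 2^((t - t_nadir) / dt_days))
}

# Closed-form day (since ADT start) when the noiseless trajectory first
# satisfies the CRPC rule: value >= min(max(2*nadir, 2), nadir + 5).
.true_crossing_day <- function(baseline, nadir, doubling_time_years,
                               decline_halflife_days) {
  threshold <- pmin(pmax(2 * nadir, 2), nadir + 5)
  t_nadir <- .nadir_day(baseline, nadir, decline_halflife_days)
  dt_days <- doubling_time_years * .DAYS_PER_YEAR
  t_nadir + dt_days * log2(threshold / nadir)
}

#' Generate a synthetic registry cohort with known ground truth
#'
#' Draws per-man trajectory parameters, simulates cause-specific deaths
#' on the 28-day grid (PCa-death hazard in the resistant phase depends on
#' the man's true kinetics risk score), lays down GnRH dispensing
#' episodes (or an orchidectomy) and noisy PSA measurements, and returns
#' both the registry tables and the generating truth.
#'
#' @param config a [generator_config()].
#' @return list with elements `cohort` (a [cohort()]) and `truth`
#'   (data.frame: `patient_id`, `true_baseline_psa`, `true_nadir`,
#'   `true_doubling_time`, `true_crpc_crossing_day` (days since ADT
#'   start, `NA` if never), `true_risk_score`, `adt_start_day`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  fu_days <- round(config$followup_years * .DAYS_PER_YEAR)
  noise_sdlog <- sqrt(log(1 + config$psa_noise_cv^2))

  pat <- vector("list", n); psa <- vector("list", n)
  disp <- vector("list", n); surg <- vector("list", n)
  vit <- vector("list", n); tru <- vector("list", n)

  age_lo <- c(55, 66, 76, 86); age_hi <- c(65, 75, 85, 94)
  age_probs <- c(0.11, 0.31, 0.44, 0.14)
  cci_probs <- c(0.627, 0.162, 0.089, 0.122)
  tx_labels <- c("Primary GnRH", "AA -> GnRH", "WW -> AA -> GnRH",
                 "WW -> GnRH", "RP -> AA -> GnRH", "RT -> AA -> GnRH",
                 "RP -> GnRH", "RT -> GnRH")
  tx_probs <- c(0.625, 0.094, 0.028, 0.122, 0.022, 0.020, 0.029, 0.060)
  adt_lo <- .day(as.Date("2006-01-01")); adt_hi <- .day(as.Date("2012-12-31"))

  for (i in seq_len(n)) {
    id <- sprintf("P%05d", i)
    coh_lab <- if (stats::runif(1) < config$cohort_split) "A" else "B"
    band <- sample.int(4L, 1L, prob = age_probs)
    age0 <- stats::runif(1, age_lo[band], age_hi[band])
    adt_start <- as.integer(round(stats::runif(1, adt_lo, adt_hi)))
    birth_year <- as.integer(format(as.Date(adt_start, origin = "1970-01-01"), "%Y")) -
      as.integer(floor(age0))
    dx_band <- sample.int(3L, 1L, prob = c(0.625, 0.158, 0.217))
    dx_lag_yr <- stats::runif(1, c(0.05, 1, 4)[dx_band], c(1, 4, 8)[dx_band])
    dx_day <- adt_start - as.integer(round(dx_lag_yr * .DAYS_PER_YEAR))
    cci <- sample(.CCI_LEVELS, 1L, prob = cci_probs)
    tx <- sample(tx_labels, 1L, prob = tx_probs)

    baseline <- stats::rlnorm(1, config$baseline_psa_log_mean,
                              config$baseline_psa_log_sd)
    frac <- min(exp(stats::rnorm(1, config$nadir_fraction_log_mean,
                                 config$nadir_fraction_log_sd)), 0.9)
    nadir <- baseline * frac
    dt_years <- stats::rlnorm(1, config$doubling_time_log_mean,
                              config$doubling_time_log_sd)
    crossing <- .true_crossing_day(baseline, nadir, dt_years,
                                   config$decline_halflife_days)
    psa_at_cross <- pmin(pmax(2 * nadir, 2), nadir + 5)
    score <- log(psa_at_cross) - 1.4 * log(dt_years)

    # cause-specific death on the 28-day grid; state by true crossing day
    p_crpc_death <- stats::plogis(config$base_pca_death_logit +
                                    config$risk_coefficient * score)
    death_day <- NA_integer_; cause <- NA_character_
    k <- 0L
    while (28L * k < fu_days) {
      in_crpc <- 28L * k >= crossing
      p_pca <- if (in_crpc) p_crpc_death else config$cspc_pca_death_prob
      ab <- as.character(age_band(age0 + 28 * k / .DAYS_PER_YEAR))
      p_oth <- config$other_cause_prob_by_age[[ab]]
      u <- stats::runif(1)
      if (u < p_pca) {
        death_day <- adt_start + 28L * k + as.integer(floor(stats::runif(1) * 28))
        cause <- "PCa"; break
      } else if (u < p_pca + p_oth) {
        death_day <- adt_start + 28L * k + as.integer(floor(stats::runif(1) * 28))
        cause <- "other"; break
      }
      k <- k + 1L
    }
    censor_day <- adt_start + fu_days
    end_day <- if (is.na(death_day)) censor_day else min(death_day, censor_day)

    # ADT exposure records
    orch <- stats::runif(1) < config$orchidectomy_fraction
    if (orch) {
      surg[[i]] <- data.frame(patient_id = id,
                              orchidectomy_date = as.Date(adt_start, origin = "1970-01-01"),
                              stringsAsFactors = FALSE)
    } else {
      day <- adt_start; disp_days <- integer(0); disp_supply <- integer(0)
      while (day <= end_day) {
        supply <- sample(c(28L, 84L, 90L), 1L, prob = c(0.8, 0.1, 0.1))
        disp_days <- c(disp_days, day); disp_supply <- c(disp_supply, supply)
        day <- day + supply
        if (stats::runif(1) < config$dispensation_gap_prob) day <- day + 28L
      }
      disp[[i]] <- data.frame(patient_id = id,
                              date = as.Date(disp_days, origin = "1970-01-01"),
                              drug_class = "GnRH", days_supply = disp_supply,
                              stringsAsFactors = FALSE)
    }

    # PSA sampling: day 0 then jittered intervals to end of follow-up
    t <- 0; tt <- 0
    while (TRUE) {
      gap <- max(7, round(config$psa_sampling_interval_days *
                            stats::runif(1, 0.5, 1.5)))
      nxt <- tt[length(tt)] + gap
      if (adt_start + nxt > end_day) break
      tt <- c(tt, nxt)
    }
    true_vals <- psa_trajectory_value(tt, baseline, nadir, dt_years,
                                      config$decline_halflife_days)
    noise <- if (config$psa_noise_cv > 0) {
      exp(stats::rnorm(length(tt), -noise_sdlog^2 / 2, noise_sdlog))
    } else rep(1, length(tt))
    psa[[i]] <- data.frame(patient_id = id,
                           date = as.Date(adt_start + tt, origin = "1970-01-01"),
                           value = pmax(true_vals * noise, 1e-3),
                           stringsAsFactors = FALSE)

    pat[[i]] <- data.frame(patient_id = id, birth_year = birth_year,
                           diagnosis_date = as.Date(dx_day, origin = "1970-01-01"),
                           cci = cci, treatment_history = tx, cohort = coh_lab,
                           stringsAsFactors = FALSE)
    vit[[i]] <- data.frame(patient_id = id,
                           death_date = as.Date(if (is.na(death_day)) NA_integer_ else
                             min(death_day, censor_day), origin = "1970-01-01"),
                           cause = cause,
                           censor_date = as.Date(censor_day, origin = "1970-01-01"),
                           stringsAsFactors = FALSE)
    tru[[i]] <- data.frame(patient_id = id, true_baseline_psa = baseline,
                           true_nadir = nadir, true_doubling_time = dt_years,
                           true_crpc_crossing_day = crossing,
                           true_risk_score = score,
                           adt_start_day = adt_start, stringsAsFactors = FALSE)
  }

  empty_disp <- data.frame(patient_id = character(0), date = as.Date(character(0)),
                           drug_class = character(0), days_supply = integer(0),
                           stringsAsFactors = FALSE)
  empty_surg <- data.frame(patient_id = character(0),
                           orchidectomy_date = as.Date(character(0)),
                           stringsAsFactors = FALSE)
  coh <- cohort(do.call(rbind, pat), do.call(rbind, psa),
                if (any(!vapply(disp, is.null, logical(1))))
                  do.call(rbind, disp[!vapply(disp, is.null, logical(1))])
                else empty_disp,
                if (any(!vapply(surg, is.null, logical(1))))
                  do.call(rbind, surg[!vapply(surg, is.null, logical(1))])
                else empty_surg,
                do.call(rbind, vit))
  list(cohort = coh, truth = do.call(rbind, tru))
}

#' Export / import the generator truth table
#'
#' Lossless CSV round trip of the per-man ground-truth parameters; an
#' absent CRPC crossing day is written as an empty field, never zero.
#'
#' @param truth truth data.frame from [generate_cohort()].
#' @param path CSV file path.
#' @return `generator_truth_table()`: invisibly, `path`;
#'   `read_truth_table()`: the truth data.frame.
#' @export
generator_truth_table <- function(truth, path) {
  out <- truth
  for (cl in names(out)) {
    if (is.double(out[[cl]])) {
      out[[cl]] <- ifelse(is.na(out[[cl]]), "",
                          formatC(out[[cl]], digits = 17, format = "g"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname generator_truth_table
#' @export
read_truth_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  num <- setdiff(names(tab), "patient_id")
  for (cl in num) tab[[cl]] <- as.numeric(ifelse(tab[[cl]] == "", NA, tab[[cl]]))
  tab
}
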