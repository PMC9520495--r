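# Fixtures built in code: a minimal hand-written registry and small
# builders shared across test files.

# A tiny valid cohort: two men on GnRH, one orchidectomy man.
tiny_cohort <- function() {
  patients <- data.frame(
    patient_id = c("a1", "b2", "c3"),
    birth_year = c(1940L, 1935L, 1948L),
    diagnosis_date = as.Date(c("2005-03-01", "2006-07-15", "2007-01-10")),
    cci = c("0", "2", "3+"),
    treatment_history = c("Primary GnRH", "WW -> GnRH", "Primary GnRH"),
    cohort = c("A", "A", "B"))
  psa <- data.frame(
    patient_id = c("a1", "a1", "a1", "a1", "b2", "b2", "c3"),
    date = as.Date(c("2006-01-01", "2006-06-01", "2006-12-01", "2007-06-01",
                     "2007-01-01", "2007-08-01", "2008-01-05")),
    value = c(25, 2, 1.5, 3.4, 18, 9, 40))
  dispensations <- data.frame(
    patient_id = c("a1", "a1", "a1", "b2", "b2"),
    date = as.Date(c("2006-01-01", "2006-04-01", "2006-07-01",
                     "2007-01-01", "2007-04-01")),
    drug_class = "GnRH",
    days_supply = c(90L, 90L, 90L, 90L, 90L))
  surgeries <- data.frame(patient_id = "c3",
                          orchidectomy_date = as.Date("2008-01-05"))
  vitals <- data.frame(
    patient_id = c("a1", "b2", "c3"),
    death_date = as.Date(c(NA, "2008-06-01", NA)),
    cause = c(NA, "PCa", NA),
    censor_date = as.Date(c("2016-01-01", "2016-01-01", "2016-01-01")))
  cohort(patients, psa, dispensations, surgeries, vitals)
}

# Homogeneous starting population for engine tests.
make_population <- function(n, state = "CSPC", risk_category = 1L,
                            age_years = 70, cci = "0") {
  data.frame(patient_id = sprintf("I%06d", seq_len(n)),
             start_state = state, risk_category = risk_category,
             age_years = age_years, cci = cci, stringsAsFactors = FALSE)
}

# Person-period table with a constant event probability, built directly.
make_person_periods <- function(n, p_event, event = "to_CRPC",
                                state = "CSPC", risk_category = 1L,
                                seed = 1) {
  set.seed(seed)
  data.frame(patient_id = sprintf("M%06d", seq_len(n)),
             state = state, period_index = 0L, days_in_period = 28L,
             age_band = "66-75", cci = "0",
             risk_category = risk_category,
             time_in_state_band = "0-6",
             event = ifelse(stats::runif(n) < p_event, event, "none"),
             stringsAsFactors = FALSE)
}
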