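day0 <- as.Date("2010-01-01")
d <- function(offset) day0 + offset
dnum <- function(offset) crpcstates:::.day(day0) + offset

disp_row <- function(offset, supply) {
  data.frame(patient_id = "x", date = d(offset), drug_class = "GnRH",
             days_supply = as.integer(supply))
}

test_that("ADT exposure is the union of supply (+grace) intervals and surgery", {
  # one 84-day supply, grace 30: days 0..113 covered
  e <- compute_adt_exposure(disp_row(0, 84), NULL, grace_days = 30)
  expect_equal(unname(e$intervals[1, ]), c(dnum(0), dnum(114)))
  expect_equal(crpcstates:::.coverage_through(e, dnum(113)), 114)
  expect_equal(crpcstates:::.coverage_through(e, dnum(114)), 114)

  # two 28-day supplies with a gap, grace 0
  e2 <- compute_adt_exposure(rbind(disp_row(0, 28), disp_row(60, 28)), NULL,
                             grace_days = 0)
  expect_equal(nrow(e2$intervals), 2)
  expect_equal(crpcstates:::.coverage_in(e2, dnum(28), dnum(59)), 0)
  expect_equal(crpcstates:::.coverage_through(e2, dnum(87)), 56)

  # orchidectomy covers from the surgery date onward
  s <- data.frame(patient_id = "x", orchidectomy_date = d(100))
  e3 <- compute_adt_exposure(NULL, s, grace_days = 30)
  expect_equal(crpcstates:::.coverage_in(e3, dnum(0), dnum(99)), 0)
  expect_equal(crpcstates:::.coverage_in(e3, dnum(100), dnum(199)), 100)
})

test_that("CSPC entry needs 90 covered days within a 183-day window", {
  # continuous supply from day 0: the 90th covered day is day 89
  e <- compute_adt_exposure(disp_row(0, 200), NULL, grace_days = 0)
  expect_equal(detect_cspc_entry(e), dnum(89))

  # a single 30-day supply can never reach 90 days
  e2 <- compute_adt_exposure(disp_row(0, 30), NULL, grace_days = 0)
  expect_true(is.na(detect_cspc_entry(e2)))

  # two 60-day supplies 200 days apart: 120 covered days but never 90
  # within one 183-day window
  e3 <- compute_adt_exposure(rbind(disp_row(0, 60), disp_row(200, 60)), NULL,
                             grace_days = 0)
  expect_true(is.na(detect_cspc_entry(e3)))

  # orchidectomy wins even with later GnRH
  s <- data.frame(patient_id = "x", orchidectomy_date = d(10))
  e4 <- compute_adt_exposure(disp_row(50, 200), s, grace_days = 0)
  expect_equal(detect_cspc_entry(e4), dnum(10))
})

test_that("nadir series is the running minimum and lags by one measurement", {
  psa <- data.frame(date = d(c(0, 30, 60, 90, 120)),
                    value = c(10, 4, 2, 3, 1.5))
  ns <- compute_nadir_series(psa, dnum(0))
  expect_equal(ns$nadir, c(10, 4, 2, 2, 1.5))
  expect_equal(ns$nadir_before, c(NA, 10, 4, 2, 2))
  expect_true(all(diff(ns$nadir) <= 0))
  # single value, and measurements before entry ignored
  ns2 <- compute_nadir_series(data.frame(date = d(c(-10, 5)), value = c(50, 5)),
                              dnum(0))
  expect_equal(nrow(ns2), 1)
  expect_equal(ns2$nadir, 5)
  expect_null(compute_nadir_series(psa, dnum(500)))
})

test_that("CRPC trigger rules: doubling >2 ng/ml, or absolute rise >= 5", {
  e <- compute_adt_exposure(disp_row(0, 365), NULL, grace_days = 0)

  run <- function(values, offsets = seq(0, by = 40, length.out = length(values))) {
    ns <- compute_nadir_series(data.frame(date = d(offsets), value = values),
                               dnum(0))
    detect_crpc(ns, e)
  }
  # nadir 1.5 then 3.1: doubled and > 2
  hit <- run(c(10, 1.5, 3.1), c(0, 100, 200))
  expect_equal(hit$day, dnum(200))
  expect_equal(hit$psa, 3.1)
  # nadir 0.5, value 1.0: doubled but not > 2, rise 0.5 < 5
  expect_null(run(c(10, 0.5, 1.0), c(0, 100, 200)))
  # nadir 0.5, value 5.6: absolute rule (5.1 >= 5)
  hit2 <- run(c(10, 0.5, 5.6), c(0, 100, 200))
  expect_equal(hit2$day, dnum(200))
  # value exactly 2 is not "> 2": no trigger via doubling
  expect_null(run(c(10, 0.9, 2.0), c(0, 100, 200)))
  # insufficient ADT at the trigger date blocks detection
  e_short <- compute_adt_exposure(disp_row(0, 40), NULL, grace_days = 0)
  ns <- compute_nadir_series(data.frame(date = d(c(0, 30, 60)),
                                        value = c(10, 1.5, 3.5)), dnum(0))
  expect_null(detect_crpc(ns, e_short))
})

test_that("PSA after the CRPC date never changes the detected date", {
  # prefix-determinedness over randomised noisy series
  e <- compute_adt_exposure(disp_row(0, 4000), NULL, grace_days = 0)
  set.seed(77)
  for (rep in 1:25) {
    n <- 40
    offsets <- sort(sample(0:3000, n))
    vals <- pmax(stats::rlnorm(n, log(3), 1), 0.01)
    ns <- compute_nadir_series(data.frame(date = d(offsets), value = vals),
                               dnum(0))
    hit <- detect_crpc(ns, e)
    if (is.null(hit)) next
    # truncate anywhere at/after the hit and re-detect
    keep <- ns$day <= hit$day
    rng <- which(keep)[sum(keep)]:nrow(ns)
    cut <- if (length(rng) == 1) rng else sample(rng, 1)
    ns2 <- ns[seq_len(cut), ]
    hit2 <- detect_crpc(ns2, e)
    expect_equal(hit2$day, hit$day)
    expect_equal(hit2$psa, hit$psa)
  }
})

test_that("state intervals follow entry, progression, death and censoring", {
  coh <- tiny_cohort()
  iv <- build_state_intervals(coh)
  # a1: GnRH from 2006-01-01 continuous 270d; entry at day 89; PSA 25 ->
  # 2 -> 1.5 -> 3.4 triggers doubling (>2) at 2007-06-01; censored
  a1 <- iv[iv$patient_id == "a1", ]
  expect_equal(a1$state, c("CSPC", "CRPC"))
  expect_equal(a1$exit_reason, c("to_CRPC", "censored"))
  expect_equal(a1$entry_day[1], crpcstates:::.day(as.Date("2006-01-01")) + 89)
  expect_equal(a1$entry_day[2], crpcstates:::.day(as.Date("2007-06-01")))
  expect_equal(a1$exit_day[1], a1$entry_day[2])
  # b2: PSA halves, never doubles; dies of PCa in CSPC
  b2 <- iv[iv$patient_id == "b2", ]
  expect_equal(b2$state, "CSPC")
  expect_equal(b2$exit_reason, "pca_death")
  # c3: orchidectomy entry on the surgery date
  c3 <- iv[iv$patient_id == "c3", ]
  expect_equal(c3$entry_day, crpcstates:::.day(as.Date("2008-01-05")))
  expect_equal(c3$exit_reason, "censored")
  # intervals are ordered and non-overlapping per man
  for (id in unique(iv$patient_id)) {
    s <- iv[iv$patient_id == id, ]
    expect_true(all(s$entry_day < s$exit_day))
    if (nrow(s) == 2) expect_equal(s$exit_day[1], s$entry_day[2])
  }
})

test_that("death before CSPC entry excludes the patient with a reason", {
  coh <- tiny_cohort()
  coh$vitals$death_date[1] <- as.Date("2006-02-01")
  coh$vitals$cause[1] <- "other"
  coh$psa <- coh$psa[!(coh$psa$patient_id == "a1" &
                         coh$psa$date > as.Date("2006-02-01")), ]
  iv <- build_state_intervals(coh)
  expect_false("a1" %in% iv$patient_id)
  excl <- attr(iv, "excluded")
  expect_true(any(excl$patient_id == "a1" & grepl("before CSPC entry", excl$reason)))
})

test_that("person-period expansion conserves time and places events in the last period", {
  iv <- data.frame(patient_id = c("p", "q", "r"),
                   state = "CSPC",
                   entry_day = c(0L, 0L, 0L),
                   exit_day = c(100L, 28L, 29L),
                   exit_reason = c("censored", "pca_death", "pca_death"))
  pats <- data.frame(patient_id = c("p", "q", "r"), birth_year = 1940L,
                     diagnosis_date = as.Date("2000-01-01"), cci = "0",
                     treatment_history = "Primary GnRH", cohort = "A")
  cats <- data.frame(patient_id = c("p", "q", "r"), cspc_category = 2L,
                     crpc_category = NA_integer_)
  pp <- expand_person_periods(iv, pats, cats)
  p <- pp[pp$patient_id == "p", ]
  expect_equal(nrow(p), 4)          # ceil(100/28)
  expect_equal(p$period_index, 0:3)
  expect_true(all(p$event == "none"))
  expect_equal(sum(p$days_in_period), 100)
  q <- pp[pp$patient_id == "q", ]
  expect_equal(nrow(q), 1)
  expect_equal(q$event, "pca_death")
  r <- pp[pp$patient_id == "r", ]
  expect_equal(nrow(r), 2)
  expect_equal(r$event, c("none", "pca_death"))
  expect_equal(sum(r$days_in_period), 29)
  # exactly one event row per ended interval
  expect_equal(sum(pp$event != "none"), 2)
})
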