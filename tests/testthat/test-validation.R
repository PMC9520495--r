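# Brute-force product-limit oracle for competing risks, written
# independently of both the package and the survival package: walks the
# unique event times, tracking the at-risk set and the overall survival
# product.
aj_bruteforce <- function(time, status) {
  # status: 0 censored, 1..K event types
  times <- sort(unique(time[status > 0]))
  K <- max(status)
  surv <- 1
  cif <- matrix(0, length(times), K)
  acc <- rep(0, K)
  for (i in seq_along(times)) {
    tt <- times[i]
    n_risk <- sum(time >= tt)
    for (k in seq_len(K)) {
      dk <- sum(time == tt & status == k)
      acc[k] <- acc[k] + surv * dk / n_risk
    }
    d_all <- sum(time == tt & status > 0)
    surv <- surv * (1 - d_all / n_risk)
    cif[i, ] <- acc
  }
  list(times = times, cif = cif)
}

make_intervals <- function(time, status) {
  # status: 0 censored, 1 to_CRPC, 2 pca_death
  data.frame(patient_id = sprintf("s%02d", seq_along(time)), state = "CSPC",
             entry_day = 0L, exit_day = as.integer(time),
             exit_reason = c("censored", "to_CRPC", "pca_death")[status + 1])
}

test_that("Aalen-Johansen on the hand-worked 5-subject table matches the oracle", {
  # events of type 1 at t=10, 30; type 2 at t=20; censored at 25 and 40.
  # Hand computation: CIF1(10)=0.2; CIF2(20)=0.8*(1/4)=0.2;
  # S(30-)=0.6, n(30)=2 => CIF1(30)=0.2+0.6*0.5=0.5
  time <- c(10, 20, 25, 30, 40)
  status <- c(1, 2, 0, 1, 0)
  iv <- make_intervals(time, status)
  obs <- observed_cumulative_incidence(iv, "CSPC")
  cif1 <- obs[obs$event == "to_CRPC", ]
  cif2 <- obs[obs$event == "pca_death", ]
  expect_equal(cif1$cif[cif1$time_days == 10], 0.2)
  expect_equal(cif2$cif[cif2$time_days == 20], 0.2)
  expect_equal(cif1$cif[cif1$time_days == 30], 0.5)

  oracle <- aj_bruteforce(time, status)
  for (i in seq_along(oracle$times)) {
    tt <- oracle$times[i]
    expect_equal(max(cif1$cif[cif1$time_days <= tt]), oracle$cif[i, 1])
    expect_equal(max(cif2$cif[cif2$time_days <= tt]), oracle$cif[i, 2])
  }
})

test_that("Aalen-Johansen matches the brute-force oracle on random censored data", {
  set.seed(41)
  for (r in 1:10) {
    n <- 60
    time <- sample(1:50, n, replace = TRUE)
    status <- sample(0:2, n, replace = TRUE)
    iv <- make_intervals(time, status)
    obs <- observed_cumulative_incidence(iv, "CSPC")
    oracle <- aj_bruteforce(time, status)
    for (k in 1:2) {
      ck <- obs[obs$event == c("to_CRPC", "pca_death")[k], ]
      for (i in seq_along(oracle$times)) {
        got <- max(0, ck$cif[ck$time_days <= oracle$times[i]])
        expect_equal(got, oracle$cif[i, k], tolerance = 1e-10)
      }
    }
  }
})

test_that("with one event type and no censoring the CIF is the empirical CDF", {
  time <- c(5, 10, 10, 20, 35)
  iv <- make_intervals(time, rep(1, 5))
  obs <- observed_cumulative_incidence(iv, "CSPC")
  c1 <- obs[obs$event == "to_CRPC", ]
  expect_equal(c1$cif[match(c(5, 10, 20, 35), c1$time_days)],
               c(0.2, 0.6, 0.8, 1.0))
  # everyone censored: flat zero
  iv0 <- make_intervals(time, rep(0, 5))
  obs0 <- observed_cumulative_incidence(iv0, "CSPC")
  expect_true(all(obs0$cif == 0))
})

test_that("AJ sanity: event CIFs plus survivors sum to one at every event time", {
  set.seed(43)
  time <- sample(1:100, 80, replace = TRUE)
  status <- sample(0:3, 80, replace = TRUE)
  iv <- data.frame(patient_id = sprintf("s%02d", 1:80), state = "CSPC",
                   entry_day = 0L, exit_day = as.integer(time),
                   exit_reason = c("censored", "to_CRPC", "pca_death",
                                   "other_death")[status + 1])
  obs <- observed_cumulative_incidence(iv, "CSPC")
  km <- survival::survfit(
    survival::Surv(time, status > 0) ~ 1)
  for (tt in km$time[km$n.event > 0]) {
    tot <- sum(vapply(unique(obs$event), function(e) {
      ce <- obs[obs$event == e, ]
      max(0, ce$cif[ce$time_days <= tt])
    }, numeric(1)))
    s <- km$surv[km$time == tt]
    expect_equal(tot + s, 1, tolerance = 1e-10)
  }
})

test_that("curve comparison reports step-interpolated differences", {
  obs <- data.frame(time_days = c(100, 400, 900), cif = c(0.1, 0.3, 0.5))
  expect_equal(compare_curves(obs, obs)$max_abs_diff, 0)
  pred0 <- data.frame(time_days = numeric(0), cif = numeric(0))
  cmp <- compare_curves(obs, pred0)
  expect_equal(cmp$max_abs_diff, 0.5)
  expect_equal(cmp$diff_2yr, -0.3)  # predicted 0 minus observed 0.3
  # a step function interpolated on a finer grid is unchanged
  fine <- data.frame(time_days = sort(c(obs$time_days, 150, 500, 800)))
  fine$cif <- crpcstates:::.step_interp(obs$time_days, obs$cif, fine$time_days)
  expect_equal(compare_curves(obs, fine)$max_abs_diff, 0)
})

test_that("outcome summary behaves at the extremes", {
  # zero hazards: full horizon in CRPC and no PCa deaths
  pop <- make_population(50, "CRPC", risk_category = 2L)
  occ <- run_microsimulation(pop, list(), constant_hazard_table(0),
                             simulation_config(replicates_per_individual = 2,
                                               horizon_periods = 130, seed = 6))
  iv <- data.frame(patient_id = pop$patient_id, state = "CRPC",
                   entry_day = 0L, exit_day = 3650L, exit_reason = "censored")
  cats <- data.frame(patient_id = pop$patient_id, cspc_category = 2L,
                     crpc_category = 2L)
  s <- summarize_outcomes(occ, iv, cats)
  row <- s[s$category_group == "1-2", ]
  expect_equal(row$predicted_time_in_crpc_yr, 9.966, tolerance = 1e-3)
  expect_equal(row$predicted_pca_death, 0)
  expect_equal(row$observed_pca_death, 0)
  expect_equal(row$observed_time_in_crpc_yr, 3640 / 365.25, tolerance = 0.01)

  # certain immediate PCa death: one period in CRPC
  models <- list(crpc_to_pca_death = constant_transition_model(
    "crpc_to_pca_death", 0.999999))
  occ2 <- run_microsimulation(pop, models, constant_hazard_table(0),
                              simulation_config(replicates_per_individual = 2,
                                                horizon_periods = 130, seed = 8))
  iv2 <- data.frame(patient_id = pop$patient_id, state = "CRPC",
                    entry_day = 0L, exit_day = 28L, exit_reason = "pca_death")
  s2 <- summarize_outcomes(occ2, iv2, cats)
  row2 <- s2[s2$category_group == "1-2", ]
  expect_equal(row2$predicted_time_in_crpc_yr, 28 / 365.25, tolerance = 1e-6)
  expect_equal(row2$predicted_pca_death, 1)
  expect_equal(row2$observed_pca_death, 1)
})

test_that("cross-validation detects a constructed miscalibration in the right direction", {
  # validation cohort progresses much faster than the training cohort:
  # the trained model must under-predict the observed CRPC incidence
  set.seed(53)
  g_slow <- generate_cohort(generator_config(n_patients = 150, seed = 71,
                                             doubling_time_log_mean = log(1.6)))
  g_fast <- generate_cohort(generator_config(n_patients = 150, seed = 72,
                                             doubling_time_log_mean = log(0.4)))
  fast <- g_fast$cohort
  fast$patients$patient_id <- paste0("F", fast$patients$patient_id)
  for (tb in c("psa", "dispensations", "surgeries", "vitals")) {
    fast[[tb]]$patient_id <- paste0("F", fast[[tb]]$patient_id)
  }
  merged <- cohort(rbind(transform(g_slow$cohort$patients, cohort = "A"),
                         transform(fast$patients, cohort = "B")),
                   rbind(g_slow$cohort$psa, fast$psa),
                   rbind(g_slow$cohort$dispensations, fast$dispensations),
                   rbind(g_slow$cohort$surgeries, fast$surgeries),
                   rbind(g_slow$cohort$vitals, fast$vitals))
  cv <- suppressWarnings(cross_validate(
    merged, simulation_config(replicates_per_individual = 20, seed = 5,
                              probability_overflow_policy = "rescale")))
  ab <- cv[cv$direction == "A->B" & cv$event == "to_CRPC", ]
  expect_lt(ab$diff_2yr, 0)
  # A = B gives internal validation: differences small on exchangeable halves
  expect_s3_class(cv, "validation_report")
})
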