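oc0 <- constant_hazard_table(0)

test_that("null dynamics: zero hazards keep everyone in the start state", {
  pop <- make_population(3, "CSPC")
  occ <- run_microsimulation(pop, list(), oc0,
                             simulation_config(replicates_per_individual = 10,
                                               horizon_periods = 130, seed = 1))
  oc <- occ$occupancy
  expect_true(all(oc$count[oc$state == "CSPC"] == 30))
  expect_true(all(oc$count[oc$state != "CSPC"] == 0))
  expect_equal(restricted_mean_time_in_state(occ, "CSPC"),
               130 * 28 / 365.25, tolerance = 1e-12)
  expect_equal(restricted_mean_time_in_state(occ, "CSPC"), 9.966,
               tolerance = 1e-3)
})

test_that("a certain event absorbs everyone in period 0", {
  pop <- make_population(5, "CRPC")
  models <- list(crpc_to_pca_death = constant_transition_model(
    "crpc_to_pca_death", 0.999999))
  occ <- run_microsimulation(pop, models, oc0,
                             simulation_config(replicates_per_individual = 4,
                                               horizon_periods = 10, seed = 2))
  cif <- predicted_cumulative_incidence(occ, "pca_death")
  expect_equal(cif$cif[cif$period == 0], 1)
  oc <- occ$occupancy
  expect_true(all(oc$count[oc$state == "PCaDeath" & oc$period > 0] == 20))
})

test_that("constant hazards reproduce the geometric closed forms", {
  n <- 20000
  p <- 0.030245
  pop <- make_population(n, "CSPC")
  occ <- run_microsimulation(
    pop, list(cspc_to_crpc = constant_transition_model("cspc_to_crpc", p)),
    oc0, simulation_config(replicates_per_individual = 1,
                           horizon_periods = 26, seed = 3))
  cif <- predicted_cumulative_incidence(occ, "to_CRPC")
  oracle <- 1 - (1 - p)^(cif$period + 1)
  se <- sqrt(oracle * (1 - oracle) / n)
  expect_true(all(abs(cif$cif - oracle) < 3 * pmax(se, 1e-4)))

  # restricted mean with a constant exit probability from CRPC
  m <- 0.0697
  pop_crpc <- make_population(n, "CRPC")
  occ2 <- run_microsimulation(
    pop_crpc, list(crpc_to_pca_death = constant_transition_model("crpc_to_pca_death", m)),
    oc0, simulation_config(replicates_per_individual = 1,
                           horizon_periods = 130, seed = 4))
  rm_sim <- restricted_mean_time_in_state(occ2, "CRPC")
  rm_oracle <- (1 - (1 - m)^130) / m * 28 / 365.25
  # SE of the mean of min(Geom, 130) occupied periods
  sd_geom <- sqrt(1 - m) / m * 28 / 365.25
  expect_lt(abs(rm_sim - rm_oracle), 3 * sd_geom / sqrt(n))
})

test_that("same seed reproduces the summary; disjoint populations merge exactly", {
  pop <- make_population(400, "CSPC")
  models <- list(cspc_to_crpc = constant_transition_model("cspc_to_crpc", 0.03),
                 cspc_to_pca_death = constant_transition_model("cspc_to_pca_death", 0.01))
  cfg <- simulation_config(replicates_per_individual = 5,
                           horizon_periods = 40, seed = 99)
  occ1 <- run_microsimulation(pop, models, oc0, cfg)
  occ2 <- run_microsimulation(pop, models, oc0, cfg)
  expect_identical(occ1$occupancy, occ2$occupancy)
  expect_identical(occ1$events, occ2$events)

  # splitting the population changes nothing: per-man substreams
  a <- pop[1:150, ]; b <- pop[151:400, ]
  occ_a <- run_microsimulation(a, models, oc0, cfg)
  occ_b <- run_microsimulation(b, models, oc0, cfg)
  merged_events <- aggregate(count ~ period + event,
                             rbind(occ_a$events, occ_b$events), sum)
  whole_events <- aggregate(count ~ period + event, occ1$events, sum)
  expect_equal(merged_events[order(merged_events$period, merged_events$event), ],
               whole_events[order(whole_events$period, whole_events$event), ],
               ignore_attr = TRUE)
})

test_that("occupancy counts partition the population and absorbing states never shrink", {
  pop <- make_population(200, "CSPC", risk_category = 5L)
  models <- list(
    cspc_to_crpc = constant_transition_model("cspc_to_crpc", 0.05),
    cspc_to_pca_death = constant_transition_model("cspc_to_pca_death", 0.01),
    crpc_to_pca_death = constant_transition_model("crpc_to_pca_death", 0.04))
  occ <- run_microsimulation(pop, models, constant_hazard_table(0.003),
                             simulation_config(replicates_per_individual = 10,
                                               horizon_periods = 80, seed = 17))
  oc <- occ$occupancy
  totals <- tapply(oc$count, oc$period, sum)
  expect_true(all(totals == 2000))
  for (s in c("PCaDeath", "OtherDeath")) {
    series <- tapply(oc$count[oc$state == s], oc$period[oc$state == s], sum)
    expect_true(all(diff(series) >= 0))
  }
  # CIFs of mutually exclusive events plus survivors account for everyone
  last <- occ$horizon - 1L
  tot_cif <- sum(vapply(c("to_CRPC", "pca_death", "other_death"), function(e) {
    cif <- predicted_cumulative_incidence(occ, e)
    cif$cif[cif$period == last]
  }, numeric(1)))
  # to_CRPC is not absorbing so its CIF overlaps the deaths; deaths +
  # survivors alone must partition
  dead <- sum(oc$count[oc$period == last & oc$state %in% c("PCaDeath", "OtherDeath")])
  alive <- sum(oc$count[oc$period == last & oc$state %in% c("CSPC", "CRPC")])
  expect_equal(dead + alive, 2000)
  expect_gte(tot_cif, 0)
})

test_that("simulated CRPC entrants draw their category from the conditional policy", {
  pop <- make_population(2000, "CSPC", risk_category = 3L)
  cond <- matrix(0, 8, 8)
  cond[3, 6] <- 1  # CSPC category 3 always becomes CRPC category 6
  for (r in (1:8)[-3]) cond[r, r] <- 1
  models <- list(
    cspc_to_crpc = constant_transition_model("cspc_to_crpc", 0.5),
    crpc_to_pca_death = suppressWarnings(fit_transition_model(
      rbind(make_person_periods(500, 0.9, event = "pca_death", state = "CRPC",
                                risk_category = 6L, seed = 31),
            make_person_periods(500, 0.001, event = "pca_death", state = "CRPC",
                                risk_category = 3L, seed = 32)),
      "crpc_to_pca_death", covariates = "risk_category")))
  occ <- run_microsimulation(pop, models, oc0,
                             simulation_config(replicates_per_individual = 1,
                                               horizon_periods = 20, seed = 7),
                             crpc_category_policy = cond)
  # if categories followed the CSPC value (3), the CRPC death hazard
  # would be ~0; with the forced draw to category 6 it is ~0.9
  cif <- predicted_cumulative_incidence(occ, "pca_death")
  expect_gt(max(cif$cif), 0.8)
})

test_that("individual trajectories respect the one-way state diagram", {
  models <- list(
    cspc_to_crpc = constant_transition_model("cspc_to_crpc", 0.15),
    cspc_to_pca_death = constant_transition_model("cspc_to_pca_death", 0.02),
    crpc_to_pca_death = constant_transition_model("crpc_to_pca_death", 0.1))
  traj <- simulate_individual(models, constant_hazard_table(0.005), "CSPC",
                              list(patient_id = "m1", risk_category = 4L,
                                   age_years = 72, cci = "1"),
                              simulation_config(replicates_per_individual = 200,
                                                horizon_periods = 60, seed = 5))
  expect_equal(dim(traj), c(200, 60))
  for (r in seq_len(nrow(traj))) {
    s <- traj[r, ]
    expect_true(all(diff(s) >= 0))                  # codes ordered CSPC<CRPC<deaths
    expect_false(any(diff(s) > 0 & s[-length(s)] >= 3))  # deaths absorbing
  }
  # overflow policy: probabilities summing above one
  models_bad <- list(
    cspc_to_crpc = constant_transition_model("cspc_to_crpc", 0.7),
    cspc_to_pca_death = constant_transition_model("cspc_to_pca_death", 0.6))
  pop <- make_population(5, "CSPC")
  expect_error(run_microsimulation(pop, models_bad, oc0,
                                   simulation_config(seed = 1)),
               class = "crpcstates_probability_overflow")
  occ_rescaled <- run_microsimulation(
    pop, models_bad, oc0,
    simulation_config(replicates_per_individual = 2, horizon_periods = 5,
                      seed = 1, probability_overflow_policy = "rescale"))
  oc <- occ_rescaled$occupancy
  expect_true(all(tapply(oc$count, oc$period, sum) == 10))
})
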