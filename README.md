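# crpcstates

Disease-trajectory modelling for castration-resistant prostate cancer
(CRPC) from registry-style longitudinal data.

Men with advanced prostate cancer on androgen deprivation therapy (ADT)
pass from a *castration-sensitive* state (CSPC — PSA controlled under
castrate testosterone) to a *castration-resistant* state (CRPC — PSA
rising despite castration) and onwards to death from prostate cancer or
other causes. `crpcstates` is for biostatisticians and epidemiologists
who want to estimate how long men spend in each state and what their
outcomes are, from nothing more than PSA measurements, drug
dispensations, surgery dates and vital status:

* **State construction** — CSPC entry after 90 days of GnRH supply
  within a 183-day window (or at orchidectomy); CRPC entry at the first
  PSA that doubles the running nadir with the value >2 ng/ml, or rises
  ≥5 ng/ml above it, on adequate ADT exposure.
* **Risk scoring** — PSA doubling time (PSADT) by log-linear least
  squares and the combined kinetics score
  `ln(PSA at CRPC) − 1.4 × ln(PSADT)`, stratified into eight
  octile-based categories per state.
* **Hazard estimation** — cause-specific per-28-day logistic models for
  CSPC→CRPC, CSPC→PCa death and CRPC→PCa death on person-period data,
  plus an age-by-comorbidity other-cause mortality table.
* **Microsimulation** — each man simulated 100× on the 28-day grid to a
  10-year horizon, with state occupancy, cumulative incidence and
  restricted mean time in state.
* **Validation** — Aalen–Johansen observed cumulative incidence under
  competing risks, observed-vs-predicted comparison, and two-cohort
  cross-validation with strict training/validation separation.
* **Synthetic registry** — a generator with known ground truth (PSA
  decline to nadir, exponential rise with known doubling time,
  dispensing episodes, cause-specific deaths), so the whole pipeline is
  testable without access to confidential register data.

## Worked example

```r
library(crpcstates)

g   <- generate_cohort(generator_config(n_patients = 300, seed = 42))
fit <- fit_pipeline(g$cohort)
sim <- simulation_config(replicates_per_individual = 50, seed = 7,
                         probability_overflow_policy = "rescale")
occ <- run_microsimulation(fit$start_population, fit$models, fit$other_cause,
                           sim, crpc_category_policy = fit$crpc_conditional)

pred <- predicted_cumulative_incidence(occ, "to_CRPC")
obs  <- observed_cumulative_incidence(fit$intervals, "CSPC")
o    <- obs[obs$event == "to_CRPC", ]
sprintf("2-yr progression to CRPC: predicted %.3f, observed %.3f",
        pred$cif[pred$period == 25], max(o$cif[o$time_days <= 730]))
#> "2-yr progression to CRPC: predicted 0.599, observed 0.616"

cross_validate(g$cohort, sim)[, c("direction", "event", "max_abs_diff",
                                  "diff_2yr", "diff_10yr")]
#>   direction     event max_abs_diff diff_2yr diff_10yr
#> 1      A->B   to_CRPC        0.056    0.033   -0.0167
#> 2      A->B pca_death        0.093    0.032   -0.0124
#> 3      B->A   to_CRPC        0.090   -0.058   -0.0093
#> 4      B->A pca_death        0.132   -0.050   -0.0437
```

The first block generates a 300-man synthetic registry, fits the full
pipeline (octile cut points, three transition models, other-cause
table), and simulates every CSPC entrant 50 times. The predicted
two-year cumulative incidence of progression to CRPC (0.599) sits
within two percentage points of the observed Aalen–Johansen estimate
(0.616). The cross-validation table fits the model on cohort A,
simulates cohort B's starting population under it (and vice versa), and
reports predicted-minus-observed cumulative-incidence differences: all
horizon differences here are within ±0.06, i.e. within Monte-Carlo
error for cohorts of ~150 men.

The fitted hazard models themselves print coefficient tables, e.g.
`fit$models$cspc_to_crpc` shows progression risk rising monotonically
across risk categories and sharply after the first six months in state.

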