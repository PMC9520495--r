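---
title: "Modelling disease trajectories through the castration-resistant state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disease trajectories through the castration-resistant state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpcstates)
```

## The model

Advanced prostate cancer treated with androgen deprivation therapy (ADT)
moves through two clinically pivotal states. A man is
*castration-sensitive* (CSPC) while his PSA stays controlled under
castrate testosterone; he becomes *castration-resistant* (CRPC) when PSA
rises despite castration. `crpcstates` reconstructs these states from
registry-style records (PSA tests, GnRH dispensations, orchidectomies,
vital status), fits discrete-time transition hazards, and microsimulates
10-year trajectories so that predicted cumulative incidence can be
validated against the observed curves.

The state space is CSPC → CRPC → PCa death, with other-cause death and
PCa death also reachable directly from CSPC, and both deaths absorbing.
Progression is one-way: a man never returns from CRPC to CSPC.

**Entry rules.** CSPC entry is the earliest day by which 90 days of GnRH
supply have accrued within a 183-day window — "3 months of treatment
within 6 months" — or the date of bilateral orchidectomy, whichever
applies. CRPC entry is the first PSA measurement that either (a) doubles
the running PSA nadir with the value strictly above 2 ng/ml, or (b)
exceeds the nadir by at least 5 ng/ml, provided at least 90 days of ADT
exposure have accrued by then. The nadir compared against is the running
minimum over *strictly earlier* measurements: a value can never be its
own nadir, which prevents a single high value from self-triggering. The
month constants (90, 183 days) and the 30-day grace period appended to
each dispensation's supply are not quantified in the source registers'
published description; they are configurable arguments with those
defaults. Whether the 90 ADT days must be *current* at the trigger date
or merely cumulative is also ambiguous in prose; the package uses the
cumulative reading (an argument available for sensitivity analysis).

**Risk scoring.** CRPC prognosis is summarised by the combined PSA
kinetics score

$$ \mathrm{score} = \ln(\mathrm{PSA_{CRPC}}) - 1.4 \times \ln(\mathrm{PSADT}), $$

where PSADT (years) is estimated by least squares of ln(PSA) on time
over the window from the date the pre-trigger nadir was attained through
the CRPC date, and clamped to [0.01, 10] years so that flat or declining
series cannot dominate. Natural logarithms are used throughout: the
score enters a fitted linear predictor, where the base only rescales
coefficients, and the published 1.4 weight originates from a model
conventionally stated on the natural scale. Both states use eight risk
categories; absent the original (unpublished) boundaries, cut points
default to the seven octiles of the training values — CSPC categories
from the last PSA within 90 days after ADT initiation, CRPC categories
from the kinetics score. Externally supplied cut points are accepted via
`risk_category_spec()`. A CRPC man with a single usable measurement (no
estimable doubling time) is categorised by PSA-at-CRPC octiles and
flagged.

**Hazards.** Events within 28-day periods are modelled by logistic
regression on person-period data, cause-specifically per transition
(CSPC→CRPC, CSPC→PCa death, CRPC→PCa death): competing events in the
same period count as non-events for the transition being fitted, and the
cause-specific probabilities are recombined in the simulation. The
default covariates are risk category (8 levels), age band (≤65, 66–75,
76–85, ≥86), Charlson Comorbidity Index class (0, 1, 2, 3+) and
time-in-state band ([0,6), [6,12), [12,24), [24,60), [60,∞) months) —
exactly the strata the register study tabulates; the published analysis
does not name its covariate set, so this default is an explicit
assumption and is configurable. Other-cause mortality uses a 16-cell
(age band × CCI) table of per-period probabilities with add-0.5
smoothing, loadable from file so an externally estimated
background-mortality model can be dropped in.

**Microsimulation.** Each man is simulated 100 times (configurable) on
the 28-day grid to a 130-period (10-year) horizon. Occupancy is recorded
at the *start* of each period and an event drawn in period $t$ is
tallied in period $t$, which makes the engine's cumulative incidence
under a constant hazard $p$ exactly $1-(1-p)^{t+1}$ and its expected
occupied periods $\sum_t (1-m)^t$ — the closed forms the test suite
verifies it against. At a simulated CSPC→CRPC transition, the man draws
a CRPC category from the training cohort's empirical conditional
distribution $P(\text{CRPC cat} \mid \text{CSPC cat})$ (add-0.5
smoothed); his time-in-state clock resets and his age band advances with
simulated time. How simulated men acquire a CRPC category is not
described in the source study; the conditional draw is this package's
choice, exposed as a pluggable row-stochastic matrix.

## Numerical and design choices

* **Dates** are day-precision; internal arithmetic uses integer day
  offsets so the 28-day grid is exact. An interval of $L$ days expands
  to $\lceil L/28 \rceil$ person-periods; the final partial period is a
  full row with its residual days recorded for time accounting, and the
  terminal event always sits in the last row.
* **Competing draws.** Within a period one categorical outcome is drawn
  with stay-probability $1-\sum p_i$. If fitted probabilities sum above
  1 the engine errors by default; a `rescale` policy divides through by
  the sum. Alternative event orderings would differ at $O(p^2)$.
* **Random numbers.** Each (man, replicate) has its own uniform
  substream keyed by a string hash of the id combined with the master
  seed, so results are independent of iteration order and of how a
  population is partitioned across calls.
* **Sparse fits.** Overparameterised logistic hazards are degenerate on
  small cohorts, so `fit_pipeline()` shrinks the covariate set with the
  event count (full set at ≥90 events, risk category alone at ≥40,
  otherwise intercept-only). Within a fit, a runaway coefficient
  (|logit| > 15) on a sparse level is replaced by the level's
  Laplace-smoothed empirical fraction; a well-populated level that
  perfectly predicts the event raises a separation error instead.
  Factor levels absent from training keep coefficient 0 with a warning
  so simulation lookups stay defined.
* **Ties and duplicates.** Same-day duplicate PSA values collapse to
  the minimum (conservative for the nadir) with a warning. A value
  exactly at a category cut point takes the lower category. If surgery
  is recorded, the orchidectomy date *is* the CSPC entry date, even if
  the GnRH rule would be satisfied around the same time.
* **Validation estimands.** Observed curves are Aalen–Johansen
  estimates on the exact-day scale (via `survival::survfit`); predicted
  curves live on the 28-day grid and are step-interpolated onto
  observed event times. Progression to CRPC is compared as a competing
  exit from CSPC (`scope = "state_exit"`); PCa death is compared from
  CSPC entry across the whole trajectory (`scope = "from_entry"`),
  because the microsimulation predicts deaths occurring after an
  intermediate CRPC transition too. Risk categories are reported as the
  four merged groups 1–2 … 7–8 by default, matching the published
  presentation.

## The synthetic registry

The original register linkages are confidential, so the package ships a
generator (`generate_cohort()`) that emulates their structure with
known ground truth. Each man's noiseless PSA trajectory declines
exponentially from a log-normal baseline (default median 30 ng/ml) to a
nadir (default ~5% of baseline, half-life 30 days) and then rises
exponentially with a log-normal doubling time (default median 0.7
years, a typical advanced-disease figure). This
decline-then-exponential-rise shape is the minimal one consistent with
the nadir and doubling-time constructs of the progression rule, and
gives the rule a closed-form crossing day — the anchor for
detection-accuracy tests. Measurements are jittered (default mean gap
60 days) with multiplicative log-normal noise (default CV 10%), so the
observed running minimum deliberately differs from the true nadir.
Dispensing is monthly 28–90-day supplies with an occasional skipped
month, exercising the grace-period logic; 5% of men are orchidectomised
instead. Deaths are drawn per 28-day period: in CRPC the PCa-death
logit is linear in the man's true kinetics score, other-cause
probabilities follow the age bands, and the age mix (11/31/44/14%
across the four bands), comorbidity and treatment-history labels follow
the published cohort composition (`swedish_registry_reference()`).

What the generator does *not* emulate: regional differences in PSA
testing intensity, metastasis status, chemotherapy, treatment switching
within CRPC, or calendar trends. Passing tests therefore demonstrate
that the pipeline recovers the quantities its own assumptions define —
rule detection, kinetics recovery, hazard calibration, cross-validated
agreement — not that those assumptions describe any particular real
registry.

## Worked example

```{r example, eval = FALSE}
g <- generate_cohort(generator_config(n_patients = 300, seed = 42))
fit <- fit_pipeline(g$cohort)
sim <- simulation_config(replicates_per_individual = 50, seed = 7,
                         probability_overflow_policy = "rescale")
occ <- run_microsimulation(fit$start_population, fit$models, fit$other_cause,
                           sim, crpc_category_policy = fit$crpc_conditional)
pred <- predicted_cumulative_incidence(occ, "to_CRPC")
obs <- observed_cumulative_incidence(fit$intervals, "CSPC")
cross_validate(g$cohort, sim)
```

On this cohort the two-year predicted incidence of progression to CRPC
is within a few percentage points of the observed Aalen–Johansen curve,
and two-cohort cross-validation (fit on A, simulate B, and vice versa)
agrees at the 2/5/10-year horizons within Monte-Carlo error — the same
checks the test suite runs.

## Problem sizes and verification

The package's own test suite runs the engine against geometric closed
forms at 20,000–50,000 simulated men, recovers known transition logits
from 200,000 synthetic person-periods, checks PSADT recovery on 500 men
with near-weekly sampling at 5% noise (Spearman ρ > 0.95), verifies the
Aalen–Johansen wrapper against a brute-force product-limit oracle, and
cross-validates exchangeable 500-man synthetic cohorts at 50 replicates
per man. Wald interval coverage is checked over 50 replicate fits.
These sizes were chosen so every Monte-Carlo comparison has a
well-defined 3-standard-error budget while the whole suite stays quick
to run.

## Known limitations

* Octile cut points are a stand-in for the original category
  boundaries; absolute category-specific numbers are therefore not
  comparable to the published ones, though orderings and calibration
  are.
* No uncertainty is propagated from the hazard fits into the simulated
  curves; predicted cumulative incidence carries Monte-Carlo noise only.
* The discrete 28-day grid makes all durations multiples of 28 days;
  events are located only to within a period.
* `detect_cspc_entry()` scans a daily indicator over the exposed range;
  pathological dispensation records spanning centuries would be slow,
  though nothing in the data model produces them.
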