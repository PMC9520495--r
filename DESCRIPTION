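Package: crpcstates
Title: Multi-State Modelling and Microsimulation of Castration-Resistant
    Prostate Cancer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs castration-sensitive (CSPC) and
    castration-resistant (CRPC) prostate cancer disease states from
    longitudinal PSA measurements and drug-dispensation records, scores
    CRPC prognosis from PSA kinetics (PSA at CRPC and PSA doubling time),
    fits discrete-time logistic hazards on a 28-day person-period grid,
    microsimulates 10-year disease trajectories, and validates predicted
    against observed cumulative incidence under competing risks.
    Includes a synthetic registry generator with known ground truth so
    the whole pipeline is testable without access to confidential
    register data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
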