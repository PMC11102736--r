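Package: sharkocc
Title: Daily Occurrence of Acoustically Tagged Sharks from Passive Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw passive-acoustic detection logs into daily
    presence/absence series and residency (degree-of-occurrence) statistics,
    and fits a hierarchical Bayesian logistic occurrence model with seasonal
    harmonic and environmental covariates, sex and length effects on the
    intercept, individual-level random slopes, and marginalization over an
    individual with unrecorded sex.  Includes posterior predictive
    binned-residual diagnostics, occurrence-probability curve prediction
    (individual, sex-specific, and population-marginal), and a synthetic-data
    generator that emulates a tagged cohort, seasonal environmental forcing,
    and the detection-stream structure the presence rule consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    coda,
    stats,
    tibble,
    tidyr,
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: JAGS (>= 4.3.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
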