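Package: migstates
Title: Never, Active and Inactive Migraine Prevalence from a Three-State
    Illness-Death Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age-specific prevalence of never, active and inactive
    migraine in three stages: inversion of the illness-death differential
    equation to recover remission rates from age-by-year prevalence and
    incidence surfaces (with resampling-based confidence bands), logit-linear
    modelling of lifetime prevalence to obtain never-migraine prevalence and
    first-incidence rates, and a deterministic discrete-time three-state
    Markov cohort producing prevalence trajectories. Includes a synthetic
    ground-truth generator emitting Global Burden of Disease style extracts
    and lifetime-prevalence tables so every stage can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
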