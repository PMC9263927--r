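Package: alsmams
Title: Multi-Arm Multi-Stage Adaptive Trial Simulation for Motor Neuron Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for multi-arm multi-stage (MAMS) adaptive
    platform trials in motor neuron disease with coprimary ALSFRS-R and
    survival outcomes. Generates synthetic cohorts with linear ALSFRS-R
    decline (random intercepts and slopes), exponential survival, dropout
    and staggered accrual; allocates participants by Pocock-Simon
    minimisation with a random element; applies a three-stage decision
    procedure on the treatment-versus-placebo slope contrast (confidence
    interval screen, one-sided 10% interim, one-sided 2.5% final) with a
    gatekept event-driven survival comparison; and estimates design
    operating characteristics (continuation probabilities, power, pairwise
    type-I error, expected sample size) by Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
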