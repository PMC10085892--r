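Package: cvdcost
Title: Individual-Level Healthcare Cost Prediction for Cardiovascular Events
Version: 0.1.0
Authors@R:
    person("Health Economics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prediction engine for individual-level annual UK healthcare costs
    associated with cardiovascular and non-vascular events. Implements published
    one-part identity-link Poisson models for annual primary care costs and
    two-part (logistic + identity-link Poisson) models for annual hospital
    inpatient costs, estimated separately for people without and with previous
    cardiovascular disease, in 2020 UK pounds. Provides recycled-prediction
    excess-cost estimation with percentile bootstrap confidence intervals, a
    synthetic person-year cohort simulator with first-occurrence events and
    absorbing death, and an estimation pipeline (quasi-likelihood GLMs with
    cluster-robust standard errors, two-part fitting, model comparison
    diagnostics and bidirectional stepwise selection) able to re-derive models
    of the same form and demonstrate parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
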