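Package: ofzmpc
Title: Offset-Free Impulsive Zone Model Predictive Control for Automated
    Insulin Delivery
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-loop insulin delivery stack for preclinical (rodent)
    artificial-pancreas studies: a five-compartment linear glucose-insulin
    model with impulsive (bolus) inputs, a disturbance-augmented Kalman
    estimator, an offset-free zone model predictive controller solved as a
    quadratic program, a virtual-subject trial simulator with unannounced
    meals and CGM artifacts, a two-stage parameter identification pipeline
    for bolus-response CGM data, and glycemic outcome metrics
    (time-in-range bands, MedARD with bootstrap confidence intervals,
    precision-based sample size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
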