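Package: mipdifx
Title: Model-Informed Precision Dosing for Infliximab Maintenance Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian forecasting of end-of-cycle infliximab trough
    concentrations from a single mid-cycle serum level. A two-compartment
    population pharmacokinetic prior (weight, albumin and anti-drug-antibody
    covariates, log-normal random effects, proportional residual error with
    censoring below the assay limit of quantitation) is conditioned on a
    patient's dosing history and timed concentration observations by
    Metropolis-Hastings sampling of the conditional parameter distribution.
    Forecasts report the median day-56 trough, 80 percent prediction
    intervals, probabilities of exceeding 5 and 10 ug/mL, and the time at
    which levels fall to a threshold. Includes a synthetic-cohort simulator
    reproducing an every-8-week maintenance design and the method-comparison
    statistics used to validate such forecasts (Deming errors-in-variables
    regression, Cohen's kappa, 2x2 diagnostic odds and likelihood ratios,
    ROC AUC with DeLong intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
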