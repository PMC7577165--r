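Package: dorapop
Title: Population Pharmacokinetics and Exposure-Response for Once-Daily Doravirine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic (PK) and exposure-response
    analysis of doravirine 100 mg once daily in antiretroviral switch trials.
    Implements a one-compartment first-order-absorption model with covariates
    on apparent clearance and volume, nonlinear mixed-effects estimation by
    Laplace approximation, empirical-Bayes post hoc individual parameters,
    steady-state exposure metrics (AUC0-24, Cmax, C24), binary week-48
    virologic endpoints under FDA-snapshot and observed-failure rules,
    logistic exposure-response modelling with AIC model comparison and
    quartile summaries, and a seeded generator of sparse-sampling trial
    datasets carrying full generative truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
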