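Package: vancotdm
Title: Vancomycin Therapeutic Drug Management with a Population Pharmacokinetic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-informed precision dosing toolkit for intravenous vancomycin
    built on a two-compartment population pharmacokinetic model with renal
    covariates (Cockcroft-Gault creatinine clearance, hemodialysis and
    continuous renal replacement therapy regimes). Provides closed-form
    concentration prediction for multiple-infusion regimens, maximum a
    posteriori (MAP) empirical-Bayes estimation of individual clearance and
    peripheral volume from measured concentrations, Monte-Carlo population
    simulation of dosing scenarios with 90% prediction intervals,
    prediction-corrected visual predictive checks, and grid search of candidate
    regimens against trough and AUC24 therapeutic targets. Reads NONMEM-style
    rectangular therapeutic drug monitoring datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
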