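Package: petnlme
Title: Population Pharmacokinetic Modelling of PET Tracer Transport Across the Blood-Brain Barrier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects (population) analysis of dynamic PET
    time-activity curves for P-glycoprotein substrate tracers such as
    (R)-[11C]verapamil. Implements a linear mammillary plasma model and a
    two-compartment brain model driven by the arterial input, categorical
    covariate machinery for efflux-inhibitor (tariquidar) and disease-group
    effects, conditional-mode (FOCE/Laplace family) marginal-likelihood
    estimation with empirical Bayes diagnostics, likelihood-ratio stepwise
    covariate selection, classical single-subject reference analyses
    (two-tissue compartment fits and Logan graphical analysis), and a
    synthetic-study generator emulating paired-scan rat and human designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
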