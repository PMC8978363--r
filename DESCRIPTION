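Package: ccmisim
Title: Multiple Imputation for Missing Covariates in Case-Cohort Studies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for evaluating multiple imputation (MI)
    strategies for missing covariate data in case-cohort studies with a
    binary outcome analysed by inverse-probability-weighted (IPW)
    regression.  Provides a sequential synthetic cohort generator modelled
    on a birth-cohort food-allergy investigation, calibrated induction of
    covariate missingness on a missingness DAG, case-cohort subsampling
    with Borgan weights, fully conditional specification (FCS) and
    multivariate normal (MVNI) imputation engines with four
    weight-accommodation strategies, weighted Poisson and logistic
    estimation with robust sandwich variance, Rubin's rules pooling, and
    simulation performance measures (relative bias, empirical and
    model-based standard error, coverage) with Monte Carlo standard
    errors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    MASS,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
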