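Package: meropk
Title: Population Pharmacokinetics and Target-Attainment Simulation for
    Meropenem in Critically Ill Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment intravenous-infusion population pharmacokinetic
    model of meropenem with a renal-function (CKD-EPI eGFR) covariate on
    clearance, log-normal inter-individual variability and a power-scaled
    proportional residual error. Provides a Laplace-based nonlinear
    mixed-effects estimation layer (objective function, covariate scan,
    nonparametric bootstrap, conditional weighted residuals, shrinkage,
    prediction-corrected visual predictive checks), external-validation
    error metrics (rBias/rRMSE), renal-function equations (Cockcroft-Gault,
    MDRD, CKD-EPI, Du Bois body surface area), Monte Carlo probability of
    target attainment (fT>MIC) simulations across dose/interval/infusion
    grids and renal-function bands, and a synthetic study generator that
    emulates a sparse ICU sampling design so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
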