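Package: lcreg
Title: Latent Class Regression with Concomitant Covariates for
    Multi-Category Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits latent class regression (mixture-of-experts) models in
    which concomitant covariates form latent classes through a
    multinomial-logit membership model and, within each class, a
    multi-category outcome is regressed on a separate set of continuous
    predictors.  Estimation is by expectation-maximisation with
    multi-start Newton inner solvers, with observed-information standard
    errors and Wald-Z effect tables.  Includes class-enumeration fit
    indices on the likelihood-ratio (L2) scale (BIC, AIC, AIC3, CAIC,
    sample-size-adjusted BIC), parametric-bootstrap likelihood-ratio
    tests for the number of classes, classification error and
    entropy-based pseudo-R2, new-case class and outcome prediction,
    multi-class confusion-table metrics under two margin conventions,
    and a synthetic cohort generator emulating a biopsychosocial
    juvenile-reoffending study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
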