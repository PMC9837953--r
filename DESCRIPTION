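Package: rdsjoint
Title: Joint Parametric Modelling of Rate, Duration and Severity of
    Recurrent Disease Exacerbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a joint parametric model for recurrent disease
    exacerbations observed as an alternating two-state process: a
    zero-inflated accelerated failure time (AFT) submodel with a subject
    random effect for the between-exacerbation gap times (event rate), an
    AFT submodel with a subject random effect for the within-exacerbation
    gap times (event duration), and a logistic submodel with a subject
    random effect for the binary severity of each event.  The three random
    effects are trivariate normal with an unstructured correlation matrix,
    so the model captures both within-subject autocorrelation and the
    interdependencies among rate, duration and severity.  Estimation is by
    maximum likelihood with adaptive Gauss-Hermite quadrature; the package
    also provides empirical-Bayes random-effect prediction, marginal mean
    and distribution-function prediction, AIC-based baseline-family
    selection, a synthetic-data generator for alternating two-state
    histories, and long-format CSV input/output with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
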