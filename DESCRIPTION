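Package: sbmcv
Title: Cross-Validation Model Selection for Stochastic Block Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the number of clusters q in sparse modular networks by
    computing leave-one-out cross-validation (LOOCV) edge-prediction errors
    analytically from belief-propagation (BP) cavity messages. Provides an
    EM/BP inference engine for the standard and degree-corrected stochastic
    block models, the Bethe free energy, Bayes/Gibbs/MAP/training prediction
    errors with per-edge standard errors, the one-standard-error selection
    rule, holdout and K-fold cross-validation via BP, a planted-partition
    generator with its detectability threshold, and an exact enumeration
    oracle for small graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
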