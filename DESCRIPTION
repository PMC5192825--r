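Package: evoinform
Title: Evolution-Informed Biomarker Selection and Outcome Prediction
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Uses evolutionary conservation estimated from protein alignments
    on a time-calibrated species tree as prior knowledge for biomarker
    discovery in clinical omics cohorts. Per-site absolute substitution rates
    are converted into gene-level evolutionary weights, combined with
    statistical association weights, and used to steer l1-penalized logistic
    regression with stability selection. Selected features feed a
    class-balanced ensemble of random forests that predicts binary clinical
    outcomes with confidence scores. Includes a synthetic-data module
    (trees, alignments, cohorts with planted signal) so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
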