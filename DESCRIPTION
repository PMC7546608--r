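Package: rsatime
Title: Time-Resolved Representational Similarity Analysis for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking stimulus representations in epoched EEG with
    time-resolved representational similarity analysis (RSA). Builds
    cross-validated neural representational dissimilarity matrices (RDMs) per
    time bin using a split-half PCA estimator, constructs predictor RDMs from
    behavioural ratings, categorical face attributes and feature-activation
    matrices, compares neural and predictor RDMs with plain and partial
    Spearman correlations, and performs Fisher-z group inference across
    participants with Benjamini-Hochberg correction across time bins. A
    forward simulator generates multichannel EEG epochs with known injected
    representational geometry so that the whole pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
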