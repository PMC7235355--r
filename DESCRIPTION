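Package: symptomnet
Title: Regularized Partial-Correlation Symptom Networks with Bridge
    Expected Influence and Bootstrap Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Gaussian graphical models over ordinal questionnaire
    items and interprets them as symptom networks. Provides item-level
    ingestion with reverse coding, detection and removal of redundant items
    via dependent overlapping-correlation tests, graphical lasso estimation
    over a penalty path with extended-BIC model selection, signed expected
    influence and bridge expected influence centralities (one- and two-step),
    nonparametric edge-weight bootstraps, case-dropping stability analysis
    with correlation-stability coefficients, bootstrapped difference tests,
    and a latent-Gaussian Likert simulator with planted network structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
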