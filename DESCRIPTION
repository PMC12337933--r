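Package: rxadhere
Title: Adherence and Drug-Utilization Pattern Analysis for Pharmacy Dispensing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for longitudinal analysis of pharmacy dispensing records in
    new-user (inception) cohorts of antihypertensive monotherapy: proportion of
    days covered (PDC) adherence with annual and whole-follow-up denominators,
    classification of drug-utilization patterns (continuation, discontinuation,
    switch, add-on), Gower-distance k-medoids risk clustering with silhouette
    based model selection, penalized (ridge/LASSO/elastic-net) logistic
    prediction models with group-survival variable selection and calibration
    diagnostics, and inverse-probability-weighted Cox models of time to high
    adherence with optional piecewise time-dependent effects. Includes a
    synthetic dispensing-record generator with planted ground truth so every
    stage of the pipeline is testable without access to proprietary dispensing
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    nnet,
    jsonlite
Suggests:
    cluster,
    pROC,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
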