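Package: aexref
Title: Reference Values for the Area Under the Expiratory Flow-Volume Curve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the area under the maximal expiratory flow-volume curve
    (AEX) from sampled traces and its landmark-based polygonal approximations
    (AEX1-AEX4) from FVC, PEF and the instantaneous flows FEF25/FEF50/FEF75.
    Builds gender- and race-stratified z-scores and lower limits of normal,
    de-novo stratified least-squares and penalized regression reference
    equations, and small mixed-activation (sigmoidal, linear, gaussian)
    neural-network reference models with holdback and pooled
    training-testing-validation schemes, boosting, and variance-based input
    importance estimated with dependent resampling over k-nearest-neighbour
    substitutes. A synthetic spirometry cohort generator emulating adult
    normal-spirometry populations makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
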