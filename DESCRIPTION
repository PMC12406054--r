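Package: gazedcm
Title: Effective Connectivity of Scene Encoding Under Free Versus Fixed
    Viewing, with Gaze Reinstatement and Memory Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits bilinear dynamic causal models (DCM) of a three-region
    visual-mnemonic network (occipital pole, parahippocampal place area,
    hippocampus) to region-of-interest BOLD time series by variational
    Laplace, performs hierarchical group inference by parametric empirical
    Bayes with Bayesian model reduction over a 128-model, family-partitioned
    modulatory model space, computes duration-weighted fixation-density
    gaze-reinstatement scores and confidence-graded memory-strength scores,
    and relates modulatory connectivity to behaviour by canonical variate
    analysis. Includes a synthetic-data generator that plants known
    connectivity, gaze, and memory effects so every stage can be validated
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    car
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
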