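Package: pestwatch
Title: Phototactic Insect Image Analysis and Pest Outbreak Warning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for light-trap pest monitoring: synthetic
    generation of falling-insect frame sequences, labelled insect image sets and
    daily moth-count series; per-pixel Gaussian-mixture background subtraction
    with rule-based capture quality control; region-of-interest cropping,
    online augmentation, stratified dataset splitting and lab/field dataset
    mixing strategies; a 30-dimensional colour/texture/shape descriptor with
    gradient-boosting feature selection; three identification models (a
    particle-swarm-optimised support vector machine, a back-propagation neural
    network, and a 56-layer full pre-activation residual network with
    transfer-learning updates); confusion-matrix evaluation; and a rule-based
    pest outbreak grading and warning engine built on 7-day count cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    xgboost,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
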