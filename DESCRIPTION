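Package: rlsaliency
Title: Reinforcement-Learning-Guided Patch Perturbation Saliency for Cell
    Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probes image classifiers with a reinforcement-learning agent
    that adds and removes bounded patch-level distortions, guided by a
    probability-dilution reward, to construct black-box adversarial
    examples, minimal perturbations, and saliency heatmaps for single-cell
    cytology images. Includes a small residual convolutional network
    backbone with sigmoid channel attention trained by cross-entropy, a
    synthetic cell-image generator with ground-truth discriminative
    regions, a tabular Q-learning attack loop, greedy perturbation
    cleanup, mask localization scoring, and a six-statistic classification
    metrics suite (accuracy, recall, precision, F-measure, specificity,
    G-means).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
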