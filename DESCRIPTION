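Package: stressaug
Title: Small-Sample Augmentation and Boosted-Tree Surrogates for Tensile Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Surrogate modelling of coarse-grained molecular-dynamics tensile
    stress from very small tabular datasets. Provides nearest-neighbor
    Gaussian interpolation (NNI) augmentation, K-means based imbalance
    detection with a Borderline-SMOTE oversampler adapted to regression
    targets, a tuned gradient-boosted surrogate with multiple-linear and
    support-vector baselines, repeated random-split robustness evaluation with
    coefficient-of-determination and coverage metrics, exact Shapley feature
    attribution by coalition enumeration, and dense response-surface
    prediction. Includes a synthetic data generator that emulates the
    statistical structure of clustered small-sample molecular-dynamics
    designs so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    MASS,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    e1071,
    xgboost
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
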