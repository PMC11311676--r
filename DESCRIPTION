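Package: prostex
Title: Texture Radiomics and False-Positive Filtering for Prostate Multiparametric MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying classical machine-learning classifiers as
    upstream false-positive filters in a prostate lesion detection pipeline
    built on multiparametric MRI (T2-weighted, ADC and diffusion-weighted
    volumes). Provides a synthetic phantom generator with nested
    gland/peripheral-zone/lesion anatomy and class-specific Gaussian
    random-field texture, volume preprocessing (z-score normalisation,
    resampling to fixed spacing, centred crop/pad), a 297-feature-per-sequence
    3D texture descriptor (Haralick statistics on gray-level co-occurrence
    matrices, 3D local binary patterns, 3D histograms of oriented gradients),
    PCA and minimum-redundancy maximum-relevance feature selection,
    class-weighted SVM, gradient-boosted tree and multilayer-perceptron
    classifiers with a seeded random hyperparameter search, region-based and
    sliding-window classification with confidence heatmaps and ROC-derived
    cutoffs, and a leakage-safe cross-validation harness with two
    pipeline-integration evaluation modes against an emulated lesion
    segmenter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
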