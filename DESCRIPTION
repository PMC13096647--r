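Package: tissuewise
Title: Tissue-Wise FDG-PET/CT Projections for Predicting Clinical-Outcome-Associated Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes whole-body CT into bone, lean, adipose and air
    compartments by Hounsfield-unit thresholding, builds tissue-wise maximum-
    and mean-intensity projections of CT and PET standardized-uptake-value
    (SUV) volumes at multiple angles about the longitudinal axis, assembles
    them into fixed-size multi-channel collages, and trains a compact
    densely-connected convolutional network to regress total metabolic tumor
    volume (TMTV), lesion count and age, or to classify sex and diagnosis
    status, under stratified k-fold cross-validation.  Includes evaluation
    statistics with bootstrap confidence intervals and paired-model
    comparisons (Steiger's Z for dependent correlations, DeLong's test for
    correlated ROC curves), Grad-CAM saliency with cohort-level aggregation
    by sex, and a synthetic whole-body phantom generator so the full pipeline
    is exercisable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
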