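Package: texturestager
Title: Texture-Based Staging of Tumor ROIs from T2-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for discriminating rectal-cancer lymph-node
    invasion status (N0 vs N1-2) from two-dimensional MRI tumor regions of
    interest. Implements intensity normalization to the ROI mean plus or minus
    three standard deviations with gray-level quantization, from-scratch
    histogram, gray-level co-occurrence matrix (GLCM) and gray-level run-length
    matrix (GRLM) texture features averaged over four directions, interobserver
    agreement via two-way random-effects intraclass correlation, univariate
    screening with a normality-gated t-test or Mann-Whitney U-test,
    forward-stepwise logistic regression with likelihood-ratio entry and
    removal, Hosmer-Lemeshow calibration, and ROC evaluation with
    Youden-optimal cutoffs. Ships a synthetic Gaussian-random-field cohort
    generator with two imaging sequences per subject and two simulated readers,
    so the full pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    png,
    RNifti,
    jsonlite,
    nortest,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
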