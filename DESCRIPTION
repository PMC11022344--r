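Package: pathdistill
Title: Semi-Supervised Assessment of Pathological Tumor Response from Slide Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates residual viable tumor percentage in annotated tumor beds
    after neoadjuvant therapy from patch-level classification of slide images.
    A frozen feature encoder feeds a two-layer classifier head trained in two
    steps: supervised on a small set of pathologist-labeled patches, then
    iteratively on pseudo-labels gated by noisy slide-level percentage
    estimates (label-space knowledge distillation). Provides slide-level
    percentage aggregation with pCR/MPR response calls, tumor-likelihood
    heatmaps, agreement metrics (R-squared, MAE, MSE, tolerance-band robust
    accuracy), and a procedural synthetic cohort generator with known ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    png,
    rlang,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    glmnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
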