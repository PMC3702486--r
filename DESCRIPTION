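Package: mclegz
Title: Infarct Heterogeneity and Peri-Infarct Gray Zone Quantification from
    Late-Enhancement Cardiac MR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates multi-contrast late enhancement (MCLE) and conventional
    inversion-recovery fast-gradient-echo (IR-FGRE) cardiac MR images of an
    infarcted left ventricle, fits per-voxel inversion-recovery signal models
    to produce T1* and steady-state maps, quantifies core infarct and
    peri-infarct gray zone by both the full-width-half-maximum (FWHM)
    thresholding rule and fuzzy C-means clustering of (T1*, steady-state)
    features, scores papillary-muscle infarct involvement, converts masks to
    grams and percent of left-ventricular mass, and runs two-group cohort
    statistics (pooled Student t from raw values or printed summaries, Fisher
    exact tests, mean-and-SD report tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    oro.nifti,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
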