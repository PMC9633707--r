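Package: whiskermap
Title: Receptive-Field Mapping and Tuning Stability in the Barrel-Cortex Whisker Map
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium-imaging receptive fields
    of layer 2/3 neurons in whisker somatosensory cortex. Identifies
    whisker-responsive cells with trial-shuffling permutation tests under
    Benjamini-Hochberg false-discovery control, computes per-cell tuning
    statistics (best whisker and equivalent best whiskers, columnar whisker
    dominance index, tuning sharpness, tuning center of mass), maps tuning
    ensembles into a normalized polar column frame, tests for local clusters
    of co-tuned neurons against within-column spatial-shuffle and
    regression-extrapolation nulls, and classifies longitudinal tuning
    stability (best-whisker changes and center-of-mass drift against
    trial-shuffle nulls) with interval subsampling and a cross-validated
    logistic model of change predictors. Includes a synthetic-data generator
    with ground-truth tuning and drift so every stage is testable.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
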