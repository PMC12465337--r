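Package: neurocult
Title: Longitudinal Morphometric and Network Analysis of Neuronal Culture Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the development and self-organisation of
    neuronal monolayer cultures from longitudinal single-channel fluorescence
    microscopy. Provides deterministic soma/neurite segmentation, skeleton
    morphometrics (neurite length, branch points), the Disaggregation Index
    and Cluster Density Factor aggregation metrics, region-based
    structure-tensor neurite coherency, baseline-normalised metric
    trajectories with fluorescence-based death-event detection and AUC
    summaries, factorial AUC regression with plate nuisance covariates and
    Benjamini-Hochberg correction, rank-based network scoring, and
    CellROX-style oxidative-stress quantification on two-channel z-stacks.
    Includes a synthetic culture-image generator with full ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    tiff,
    EBImage,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
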