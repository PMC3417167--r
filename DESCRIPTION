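Package: socmap
Title: Annotation-Driven Mapping of Social Perception Networks in Naturalistic fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for mapping brain networks that track continuously annotated
    stimulus features in naturalistic fMRI. Continuous two-rater prominence
    ratings of social and non-social features become regressors on the
    acquisition grid (rater averaging, clip concatenation, within-TR
    down-sampling, optional canonical HRF convolution, discrete-cosine drift
    basis, mutual regressor orthogonalization with a weight ledger).
    Mass-univariate AR(1)-prewhitened GLMs yield per-feature beta/t/p maps,
    social-versus-non-social contrasts, second-level random-effects tests with
    voxelwise Benjamini-Hochberg FDR control, and cumulative overlap maps.
    Spherical-ROI summaries feed a functional-connectivity graph thresholded by
    a circular-shift permutation null, whose community structure is found by
    two-level map-equation (description length) minimization with restarts.
    A synthetic-data module generates rating tracks and 4D BOLD series with
    planted region-specific effects so the whole pipeline is verifiable by
    parameter and structure recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
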