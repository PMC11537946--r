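Package: octamorph
Title: Vascular Morphometry and Quality Assessment for Paired OCTA Projection Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of en-face optical coherence
    tomography angiography (OCTA) projection maps, built for comparing a
    translated or reconstructed arm against a device-acquired ground-truth
    arm. Computes four vascular morphometry features (blood vessel density,
    caliber, tortuosity and vessel perimeter index) via binarization,
    centerline skeletonization, branch decomposition and sub-pixel contour
    extraction; image-quality metrics (SSIM, PCQI and the Frechet distance
    between embedded image sets); and cohort-level statistics (per-group
    mean and SD tables with two-tailed t-tests between arms). Ships a
    seeded synthetic vascular-network generator with a parametric
    degradation model so the whole pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
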