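Package: flapmetrics
Title: Craniectomy Surface Area Estimation from Volumetric Skull Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to reconstruct the skull flap removed at decompressive
    craniectomy from pre- and post-operative volumetric bone masks and to
    estimate its outer surface area three ways: a normal-filtered marching
    isosurface estimator, a Cauchy-Crofton quasi-Monte Carlo estimator
    driven by a four-dimensional Sobol sequence, and the simple AC
    (greatest axial length times height) product. Includes a synthetic
    spherical-dome skull phantom generator with analytically known flap
    areas, mask-based rigid registration and subtraction preprocessing,
    and Bland-Altman style agreement statistics for comparing the
    estimators across case cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
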