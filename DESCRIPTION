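Package: vesselphantom
Title: Cohort-Averaged Vascular Anatomy Models and Printable Flow Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build cohort-averaged models of branching vascular
    anatomy (abdominal aortic aneurysm and aortoiliac trees) from per-patient
    lumen surface meshes and center lumen lines: equal arc-length centerline
    resampling, perpendicular cross-sectional lumen quantification with
    circular-equivalent diameters, index-wise cohort averaging with spread
    statistics, watertight tube-and-junction surface reconstruction with a
    thin printable wall, and quality assessment via the Sorensen-Dice
    similarity coefficient and closest-point mesh distance maps. Also
    implements through-transmission acoustic characterization mathematics
    (two-thickness attenuation spectra, cross-correlation speed of sound
    against a water reference with first-order uncertainty propagation) and
    axisymmetric volumetric-flow integration of radial velocity profiles.
    Includes synthetic vessel-tree and tone-burst generators with known
    ground truth so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
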