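Package: biofilmorph
Title: Mechanics and Morphometrics of Wrinkling and Delaminating Bacterial Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing growth-induced mechanical instabilities in
    bacterial biofilms. Implements a trilayer (film / residual layer /
    substrate) linear-stability model of wrinkling that predicts the critical
    wavelength, stress and strain from layer moduli and thicknesses; a
    plane-strain neo-Hookean finite-element simulator of confined film growth
    with multiplicative growth decomposition and wrinkle-onset detection;
    colony image and contour morphometrics (intensity normalisation,
    segmentation, ring-FFT stripe counting, acircularity, expansion-velocity
    breakpoints, local curvature and boundary velocity, blister height and
    width); seeded synthetic-data generators for all of these; and a small
    reproducible pipeline layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
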