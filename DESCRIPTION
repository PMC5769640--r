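Package: flapwing
Title: Two-Dimensional Aerodynamics of Flapping Insect Wing Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the two-dimensional unsteady incompressible flow around
    flapping insect wing cross-sections driven by prescribed bee-like
    kinematics. Provides parametric generators for the four cross-sections
    commonly compared in the insect-flight literature (a corrugated bee-like
    section with vein thickenings and a fore/hind interface notch, its
    smoothed approximation, an ellipse and a flat plate), a fixed-Cartesian
    grid fractional-step Navier-Stokes solver with Brinkman volume
    penalization for the moving wing, lift and drag coefficient extraction,
    and cross-section comparison statistics (cycle averages and root mean
    square differences of coefficient traces). Includes the hovering
    flat-plate validation case and a four-section forward-flight sweep as
    packaged studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
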