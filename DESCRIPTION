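Package: tcfus
Title: Full-Wave Acoustic and Bioheat Simulation for Transcranial Focused
    Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-difference time-domain (FDTD) solvers for the linear
    acoustic pressure wave equation with a density-variation term and for
    the nonlinear Westervelt-Lighthill equation, on 3D rectilinear grids
    truncated by convolutional perfectly matched layers.  Includes a
    phased-array transducer model, four skull-aberration correction
    strategies (distance-based, ray-traced, and two time-reversal
    variants), a Pennes bioheat solver coupled to the acoustic field
    through relaxation absorption, synthetic phantoms (plane-wave
    interface slabs, baffled pistons, spherical-shell skulls), and
    analytic references and focal-region metrics for validation of
    transcranial focused ultrasound simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    withr,
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
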