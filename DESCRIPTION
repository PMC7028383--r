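Package: threephoton
Title: Photon Budget, Tissue Heating and Depth Limits for Two- and
    Three-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative framework for comparing 920-nm two-photon and
    1320-nm three-photon calcium imaging in scattering brain tissue.
    Implements shot-noise-limited calcium-transient discriminability and
    minimum photon budgets, nonlinear excitation scaling and effective
    attenuation length (EAL) calibration, three-photon fluorophore
    saturation, weighted Monte Carlo light transport through an underfilled
    objective into tissue, a Pennes bio-heat solver for brain heating under
    continuous scanning, a signal-to-background-ratio depth-limit model with
    staining inhomogeneity, a calcium-trace and image measurement pipeline
    with Poisson likelihood spike inference, an imaging-parameter planner,
    and synthetic-data generators that emulate the corresponding in vivo
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
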