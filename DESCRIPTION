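Package: muellermc
Title: Polarized Monte Carlo Simulation and Logarithmic Mueller Matrix
    Decomposition for Tissue Polarimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transmission Mueller matrix modeling of thin turbid slabs such as
    histological tissue cuts. Simulates polarized photon transport through
    slabs containing monodisperse spherical (Mie) and infinitely long
    cylindrical scatterers embedded in an isotropic or uniaxial linearly
    birefringent host medium, assembles the forward-scattering Mueller matrix
    image, and analyses it with the logarithmic Mueller matrix decomposition
    (LMMD). Provides the rotation-invariant LMMD parameters (total linear
    retardance and dichroism, circular birefringence and dichroism, isotropic
    and anisotropic linear depolarization, circular depolarization), named
    presets for sphere-cylinder (SC), sphere-birefringence (SB) and
    sphere-cylinder-birefringence (SCB) optical models of the skin dermal
    layer, thickness-sweep experiments with trend fits, and a
    model-discrimination report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
VignetteBuilder: knitr
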