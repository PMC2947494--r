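Package: memslab
Title: Implicit-Membrane Continuum Electrostatics via the Linearized
    Poisson-Boltzmann Equation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds dielectric, ion-accessibility and charge maps from
    atomic structures in PQR format, inserts an implicit membrane slab
    (with head-group layers and pore exclusion cylinders) into those
    maps, and solves the linearized Poisson-Boltzmann equation on
    regular grids with electrostatic focusing and transmembrane-potential
    boundary conditions.  Provides the three standard membrane-protein
    energy workflows: protein solvation, ion solvation, and gating-charge
    (voltage-sensor valence) calculations.  Grids are read and written in
    OpenDX format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
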