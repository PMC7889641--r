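Package: condensr
Title: Coarse-Grained Simulation and Analysis of Salt-Dependent Protein
    Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-resolution coarse-grained modelling of protein
    liquid-liquid phase separation under varying electrostatic screening.
    Implements a hydrophobicity-scale (HPS) pair potential with
    Debye-Hueckel electrostatics, salt-regime interaction scaling and an
    optional cation-pi well; Langevin (BAOAB) dynamics in periodic slab
    geometries for direct-coexistence simulations; density-profile and
    coexistence-density analysis with critical-point fitting; a WHAM
    solver with Bayesian-bootstrap errors for umbrella-sampling free
    energy profiles; inter-chain contact maps and droplet morphology
    metrics; and synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    Biostrings,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff
Config/testthat/edition: 3
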