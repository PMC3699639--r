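Package: sepcm
Title: Semi-Empirical NDDO Electronic Structure with Conductor-Like PCM Solvation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained semi-empirical quantum chemistry engine (MNDO, AM1
    and PM3 for H, C, N and O) coupled to the conductor-like polarizable
    continuum model (C-PCM) of solvation. Provides NDDO two-center multipole
    integrals, restricted closed-shell SCF with DIIS, GEPOL cavity tessellation
    with Gauss-Bonnet exposed areas, apparent-surface-charge electrostatics,
    electrostatic solvation free energies, energy gradients (numerical core plus
    analytic solvent-field terms), BFGS geometry optimization, double-difference
    Hessians with harmonic frequencies, and a driver that reproduces a
    twenty-cation aqueous solvation benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
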