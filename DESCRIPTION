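Package: ephapse
Title: Ephaptically Coupled Axonal Sheets: Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates electrical (ephaptic) interactions between the densely
    packed axons of white-matter fiber sheets. Implements two coupled models:
    a discrete system of N FitzHugh-Nagumo axonal cables coupled all-to-all
    through a shared resistive extracellular space, and its continuous-limit
    two-dimensional field approximation. Both are integrated with an
    implicit-explicit Crank-Nicolson scheme with zero-flux boundaries.
    Includes reproducible stimulation protocols (boxcar impulses and seeded
    Poisson spike trains) and the analysis toolkit needed to characterise the
    emergent dynamics: spike rasters, impulse-lag and phase-locking series,
    traveling-front widths, backward-propagation detection, mean
    interspike-interval tables, spatial Fourier spectra and their cross-model
    cosine similarity, and a qualitative regime classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
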