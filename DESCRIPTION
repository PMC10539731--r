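Package: masmoments
Title: Residual Dipolar Line Broadening Under Magic-Angle Spinning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of residual homonuclear dipolar line broadening in
    magic-angle spinning (MAS) solid-state NMR of small proton spin systems.
    Builds rotor-periodic dipolar Hamiltonians from spin coordinates via rank-2
    Wigner rotations, constructs effective Hamiltonians by Floquet expansion
    (orders one to three) or numerically exactly from the matrix logarithm of
    the rotor-period propagator, and derives powder-averaged stick spectra,
    spectral moments, Gaussian-equivalent line widths, and line-shift,
    line-width and second-moment scans versus spinning frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
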