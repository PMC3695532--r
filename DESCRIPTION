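Package: spinspy
Title: Simulation of Indirect 14N Detection NMR Under Magic-Angle Spinning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact two-spin (13C-14N) density-operator simulation of
    spy-nucleus experiments that detect nitrogen-14 indirectly through an
    adjacent carbon-13 under magic-angle spinning. Coherence between the
    spin-1 14N and the spin-1/2 13C is generated by long, moderate-amplitude
    continuous rf pulses on 14N; the Hamiltonian includes the first-order
    quadrupole interaction, second-order quadrupole self and quadrupole-dipole
    cross terms, heteronuclear dipolar and J couplings, rf fields and offsets.
    Provides ZCW-style three-angle powder averaging, rotor-period propagator
    caching, coherence-order filtering and phase cycling, HMQC-type 1D/2D
    experiment runners, parameter scans (pulse length, rf amplitude, offset),
    and hypercomplex States spectral processing with ppm referencing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
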