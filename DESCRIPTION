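Package: vibhb
Title: One-Dimensional Nuclear Quantum Vibrational Analysis of Hydrogen Bonds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the one-dimensional nuclear Schroedinger equation on
    tabulated proton-migration potential energy curves using a
    Colbert-Miller discrete variable representation, and derives the
    observables used to characterise strong hydrogen bonds: vibrational
    energy levels, zero-point energies, vibrationally averaged and
    Boltzmann thermally averaged bond lengths, H/D isotope comparisons,
    and a barrier-versus-zero-point-energy classification of low-barrier
    hydrogen bonds. Includes analytic model potentials (harmonic, Morse,
    asymmetric double well) and fixtures calibrated to the Glu46-pCA
    hydrogen bond of photoactive yellow protein.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
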