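Package: debyesim
Title: Multipole Debye Dispersion Modelling and Time-Domain Simulation of
    Biological Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents the dielectric dispersion of biological tissue as a
    multipole first-order Debye model, fits the model to admittance spectra
    from impedance spectroscopy with a genetic algorithm minimising a
    log-space cost over the measured band, and simulates the tissue's
    terminal electric current in both frequency and time domains.  The
    time-domain path uses the auxiliary-differential-equation (ADE) method,
    available both as a lumped (uniform-field) solver and as a minimal
    axisymmetric finite-element solver for quasi-static electric currents.
    Includes a synthetic-spectrum generator emulating a 40 Hz-10 MHz
    plate-electrode impedance sweep for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
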