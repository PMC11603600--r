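Package: vtst
Title: Variational Transition State Theory Rate Constants with Hindered
    Rotors and Eckart Tunneling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gas-phase thermal rate constants from electronic-structure
    data via the thermodynamic formulation of transition state theory
    (TST) and canonical variational TST (CVT).  Builds the minimum-energy
    path from intrinsic reaction coordinate (IRC) profiles, locates the
    transition-state zone by reaction force analysis, and minimizes the
    generalized rate constant over computed path points.  Torsional modes
    are treated with one-dimensional hindered-rotor partition functions
    (Pitzer-Gwinn and a polynomial-corrected variant in the style of
    Ayala and Schlegel), validated against an exact periodic torsional
    eigensolver.  Tunneling is included through the one-dimensional
    asymmetric Eckart barrier.  Ships a synthetic-fixture generator so
    the whole pipeline is testable without any quantum-chemistry program.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
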