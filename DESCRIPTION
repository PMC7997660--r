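Package: unwindr
Title: Single-Molecule Analysis of Helicase DNA Hairpin Unwinding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing constant-force optical-trap recordings of
    helicase-mediated DNA hairpin unwinding. Converts tether extension to base
    pairs unwound with an extensible worm-like chain model, detects discrete
    steps and transient ssDNA-binding-protein melting events, segments traces
    into unwinding bursts with processivity and velocity statistics, and fits a
    four-state processivity-switch kinetic model (low/high processivity,
    dissociated, threshold-crossed) to first-passage-time data globally across
    protein concentrations, with a closed-form first-passage solution and a
    Gillespie simulator for synthetic traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
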