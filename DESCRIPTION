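Package: quadbind
Title: Host-Guest Binding and Thermal Stability Analysis for
    Peptide-G-Quadruplex Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Equilibrium speciation solvers for 1:1 and 2:1 host-guest
    binding, global nonlinear fitting of fast-exchange NMR chemical-shift
    titrations with AICc-based stoichiometry model comparison, circular
    dichroism melting-curve analysis (asymmetric sigmoid fits, melting
    temperature at the half-denaturation point, fraction-folded
    normalization, stabilization tables), G-quadruplex CD topology
    classification, free-energy and selectivity arithmetic, saturation
    design simulations, and seeded synthetic-data generators emulating the
    corresponding instrument experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
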