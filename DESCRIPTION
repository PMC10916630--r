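Package: shelfkin
Title: Storage-Stability Kinetics and Shelf-Life Prediction for Soymilk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for accelerated shelf-life analysis of soymilk and
    similar colloidal beverages: closed-form quality indices (centrifugal
    sedimentation rate, stability coefficient, Stokes sedimentation
    velocity), zero- and first-order storage kinetics, Arrhenius
    activation-energy estimation, Eyring transition-state thermodynamics
    with a Gibbs-energy-versus-temperature regression, a combined
    kinetic-sensory shelf-life model with residual-variation validation,
    and a seeded synthetic-data generator for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
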