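Package: wlctube
Title: Wormlike Chains Stretched in Rectangular Tubes and Slits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical mechanics of semiflexible (wormlike) polymer chains
    simultaneously confined in rectangular tubes or slits and stretched by an
    axial force, in the Odijk deflection regime. Provides closed-form
    confinement free energies and force-confinement-extension relations built
    on a modified deflection length; a ground-state eigenvalue solver for the
    Fokker-Planck equation of a slit-confined chain; a generalized bead-rod
    (GBR) Brownian dynamics simulator with inextensible rod constraints and
    hard channel walls; and trajectory analysis tools that reduce simulations
    to equilibrated mean extensions with uncertainties for comparison against
    the theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
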