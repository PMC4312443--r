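Package: rhocycle
Title: Simulation of the Rho GTPase Cycle with GDI-Mediated Inhibition of
    GEFs and GAPs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation models of the Rho
    GTPase activation cycle in which RhoGDI both sequesters the GTPase and
    non-competitively inhibits the catalytic activities of guanine nucleotide
    exchange factors (GEFs) and GTPase-activating proteins (GAPs). Provides
    four model variants (canonical sequestration-only regulation, the fully
    GDI-integrated model, and single-interaction knockouts), a stiff ODE
    simulator with conservation-law checking, activation-dynamics metrics
    (peak, half-decay time, sustained ratio), parameter-scan drivers over
    free-GDI levels, inhibition constants and regulator concentrations,
    SBML import/export, and a seeded log-uniform parameter-perturbation
    generator for robustness analysis of the qualitative conclusions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
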