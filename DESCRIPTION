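Package: screlease
Title: Two-Step Diffusion-Desorption Modelling of Thermal Radioscandium
    Release from Titanium Targets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and fitting pipeline for the thermal release of
    radioscandium from heated titanium foil targets in vacuum.  Implements a
    two-step release model (Fickian slab diffusion of Sc atoms to the foil
    surface in its first-term approximation, followed by Frenkel
    adsorption-desorption into vacuum), a seeded Monte Carlo atom-history
    engine with a semi-analytic quadrature oracle, grid-search least-squares
    extraction of the Sc/Ti desorption enthalpy from release-versus-condition
    measurements with bootstrap uncertainties, release and catcher-recovery
    bookkeeping, and a synthetic-data generator emulating gamma-counting
    measurement noise.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
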