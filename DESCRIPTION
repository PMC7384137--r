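Package: aicdosim
Title: Coupled Capillary Hemodynamics and Alpha-Particle Microdosimetry
    for Alpha-Immuno-Conjugate Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the transport of alpha-immuno-conjugate (AIC)
    aggregates through a two-dimensional blood-capillary lumen and the
    resulting time-dependent microdosimetric specific energy delivered to a
    nearby cell nucleus.  Couples an incompressible finite-volume flow
    solver with a ghost-cell immersed-boundary treatment of the particles,
    a hard-sphere collision model, Bateman decay kinetics for the
    radionuclide payload, and a Monte Carlo single-hit specific-energy
    model with a deterministic quadrature cross-check.  Includes a
    stationary-source reference mode for quantifying how blood convection
    redistributes the absorbed dose relative to the conventional motionless
    source assumption in targeted alpha therapy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
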