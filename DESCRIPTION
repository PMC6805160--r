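Package: anttraffic
Title: Fundamental Diagrams and Microscopic Dynamics of Bidirectional Ant Traffic
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing bidirectional traffic on ant foraging trails.
    Fits classical flow-density relations (Greenshields, Pipes-Munjal,
    Underwood) and a two-phase piecewise-linear flow function to per-second
    flow/density observations by nonlinear least squares, and selects among
    them with Akaike weights.  Implements the microscopic chain linking local
    density to contact rate, contact count to travel time, and a
    pheromone-modulated speed model with its predicted flow and closed-form
    limit flow; converts ant morphology to per-ant area and trail occupancy;
    and regresses flow on density and directional asymmetry with standardized
    coefficients.  A seeded statistical generator produces synthetic
    macroscopic and individually-tracked records with the error structure the
    analysis assumes, so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
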