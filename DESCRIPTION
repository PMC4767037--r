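Package: gutsim
Title: Mechanistic Simulation of Gastric Emptying, Luminal Mass Transfer
    and Starch Digestion in the Human Gut
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A compartmental reactor model of the upper gastrointestinal
    tract: a perfectly mixed stomach that empties exponentially into a
    plug-flow small intestine where glucose is absorbed through a
    viscosity-dependent luminal mass-transfer coefficient (laminar
    Sherwood correlation with Stokes-Einstein diffusivity) and starch is
    hydrolysed to glucose by Michaelis-Menten kinetics. Provides
    method-of-lines solvers (first-order upwind advection) for the
    dimensional and dimensionless forms of the three model variants,
    independent closed-form and method-of-characteristics verification
    oracles, characteristic-time (regime) analysis, parameter-sweep
    drivers that regenerate viscosity, emptying and reaction regime maps,
    and a command-line interface with YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
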