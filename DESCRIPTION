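Package: clockAIF
Title: Antithetic Integral Feedback Control of Circadian Clock Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Power-law (extended S-System) modeling of circadian gene
    networks under square-wave light-dark forcing, and a design framework
    for antithetic integral feedback (AIF) controllers that restore a clock
    gene's circadian profile after loss-of-function of one of its positive
    regulators. Provides S4 containers for models, light schedules,
    trajectories and reference signals; an event-aware ODE simulator;
    normalized least-squares parameter estimation by Nelder-Mead;
    closed-loop simulation of the two-species sequestration controller;
    the sequestration-rate design bound and reference-tracking mean square
    error; and automated parameter sweeps implementing a five-step
    controller tuning procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    deSolve,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'light.R'
    'ssystem.R'
    'simulate.R'
    'clocks.R'
    'reference.R'
    'estimation.R'
    'aif.R'
    'design.R'
    'io.R'
    'cli-helpers.R'
    'show-methods.R'
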