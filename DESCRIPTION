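Package: eatdry
Title: Equivalent Accumulated Temperature Control for Continuous Grain Drying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models and closed-loop control of continuous mixed-flow grain
    drying based on the equivalent accumulated temperature (EAT) mutual-window
    method. Provides Weibull thin-layer drying kinetics with nonlinear fitting
    and a synthetic thin-layer data generator, the three-parameter CAE
    desorption equilibrium temperature model, accumulated-temperature
    calculators for deep beds divided into drying, tempering and cooling
    zones, a discrete-event simulator of a six-section continuous dryer, and a
    window-selection / window-adjustment / window-adaptation controller that
    corrects its internal drying model with a real-coded genetic algorithm and
    actuates the grain discharge interval. Ships scenario presets for
    continuous operation and step, pulse and sinusoidal disturbances, CSV run
    logs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
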