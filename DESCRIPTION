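Package: crystplan
Title: Closed-Loop Experiment Planning for Batch Cooling Crystallization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Plans batch cooling crystallization experiments that steer
    measured kinetics (induction time, nucleation rate, growth rate) toward
    target values. Implements two closed-loop planners: adaptive design of
    experiments with physics-smoothed response-surface minimization over an
    ensemble of global optimizers, and Bayesian optimization with a
    Gaussian-process surrogate, expected-improvement acquisition and an
    adaptive jitter schedule that shifts from exploration to exploitation as
    the objective falls. A stochastic virtual laboratory built from the same
    kinetic relations (exponential induction times with right-censoring at
    the isothermal hold, multiplicative noise on rates) lets campaigns be
    exercised and compared without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
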