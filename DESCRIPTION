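Package: amtrack
Title: Adaptive Up-Down Threshold Tracking and Simulated
    Amplitude-Modulation Detection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for auditory psychophysics: transformed
    up-down (n-down-1-up) adaptive staircases with step-size schedules,
    calibrated synthesis and multichannel mixing of amplitude-modulated
    tone stimuli, a simulated-observer three-alternative forced-choice
    amplitude-modulation detection experiment, convergence statistics for
    staircase validation, and latency/jitter characterization of
    event-marker streams. The front end is a single experiment runner
    returning a classed object with the usual print, summary, coef,
    residuals, plot and simulate methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
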