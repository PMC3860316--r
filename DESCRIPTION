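Package: rdksim
Title: Simulation of Random Dot Kinematogram Psychophysics with Adaptive Staircases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation pipeline for global-motion psychophysics with random
    dot kinematograms (RDKs). Generates limited-lifetime signal/noise dot
    stimuli, simulates observers responding in a two-alternative
    direction-discrimination task (a descriptive Weibull psychometric observer
    and a mechanistic capacity-limited "undersampling" observer that reads the
    dot frames), runs three-down/one-up adaptive coherence staircases with
    reversal-based geometric-mean threshold estimation and interleaved
    response-bias catch trials, and assembles these into factorial experiment
    drivers (dot density x animation frames; coherent-prime contrast effect)
    with tidy result tables and summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    ggplot2,
    yaml
Suggests:
    png,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
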