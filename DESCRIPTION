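Package: vigilarch
Title: Sleep-Wake Architecture Analysis and Simulation for Rodent EEG Studies
Version: 0.1.0
Authors@R:
    person("Vigilarch", "Maintainers", email = "maintainers@vigilarch.invalid",
           role = c("aut", "cre"))
Description: Tools for analysing rodent vigilance-state recordings: episode
    segmentation with interruption tolerance, brief-awakening detection,
    state-transition statistics, time-in-state accounting, per-epoch EEG
    spectral analysis with slow-wave-activity time courses, immobility-defined
    sleep scoring from video tracking, and a chi-square periodogram for
    circadian activity. Includes a calibrated semi-Markov hypnogram simulator
    with state-conditional EEG/EMG and mobility synthesis, and a pipeline that
    produces group-comparison tables for wild-type versus mutant cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
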