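Package: cardiogate
Title: Cardiac-Gated Stimulus Timing, Interoception Scoring and
    Default-Prior Bayesian Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cardiac psychophysiology experiments in which task
    cues are locked to phases of the cardiac cycle. Implements the
    real-time scheduling rule that anchors systole cues 290 ms after a
    detected ECG R-wave and diastole cues 10 ms before the next R-wave
    predicted from the median of the three preceding inter-beat
    intervals, together with an achieved-timing evaluation in 50 ms
    bins. Scores the heartbeat-tracking interoception task (standard and
    alternative accuracy, insight, awareness, confidence, sensibility
    and trait interoceptive prediction error), computes RMSSD heart-rate
    variability, and scores Go/NoGo/Choose intentional-inhibition
    sessions. Frequentist tests are paired with their default-prior
    Bayesian counterparts (Jeffreys-Zellner-Siow t-test and regression
    Bayes factors, stretched-beta correlation Bayes factors), all
    computable from either raw columns or printed summary statistics. A
    synthetic-data generator with known ground truth makes the full
    pipeline testable without any recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
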