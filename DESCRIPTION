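Package: kinestim
Title: Simulation and Analysis of Movement State-Dependent Closed-Loop
    Deep Brain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale emulation and analysis of a speed-selective
    closed-loop subthalamic deep brain stimulation experiment. Generates
    synthetic tablet reaching-task cursor traces with minimum-jerk speed
    profiles, a bradykinetic per-trial decrement and an injectable
    direction-specific reinforcement effect; emulates the real-time
    controller (streaming six-sample speed smoothing, online peak
    detection, two-back fast/slow classification, 300-ms burst
    scheduling); implements the offline behavioural pipeline (movement
    bounds, block speed-change normalisation with outlier handling,
    direction-resolved post-stimulation speed shifts); provides paired,
    independent, sign-flip and cluster permutation tests; and performs
    artifact-aware Morlet time-frequency analysis of sensorimotor beta
    power around stimulated movements.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
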