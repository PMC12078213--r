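Package: ocutrack
Title: Oculometric Analysis of Visually-Driven Ocular Tracking
Version: 0.1.0
Authors@R: person("Ocutrack", "Maintainers", email = "maintainers@ocutrack.dev",
    role = c("aut", "cre"))
Description: Simulation and analysis of radial step-ramp ocular tracking
    sessions. Generates synthetic cohorts of gaze and pupil recordings with
    known ground truth, extracts per-trial kinematic features (pursuit onset,
    open-loop acceleration, steady-state velocity, catch-up saccades, pupil
    step responses), aggregates them into an 18-oculometric profile per run,
    computes directional tuning in world and retinal coordinates with
    chi-square circularity tests, runs the paired condition-comparison
    statistical battery (t, Wilcoxon, exact binomial sign tests), and fits a
    shunting-inhibition model of binocular pupillary summation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
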