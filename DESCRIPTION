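Package: spiralburst
Title: Subthalamic Beta Bursts and Spiral-Drawing Kinematics
Version: 0.1.0
Authors@R:
    person("Open", "Neurokinetics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for subthalamic local field potentials (LFP)
    recorded during spiral drawing in Parkinson's disease, with and without
    deep brain stimulation (DBS). Implements burst detection of beta-band
    (13-30 Hz) oscillations against rest-derived percentile thresholds,
    spiral kinematics (tangential velocity, radius-angle transform, spiral
    fit), Morlet time-frequency maps with time-warping and cluster-based
    permutation statistics, multitaper band power, peri-burst acceleration
    analysis with linear-grid and shuffled-onset null controls, and
    trial-level linear mixed-effects and correlation statistics. Ships a
    synthetic cohort generator with known ground truth (injected bursts,
    burst-locked decelerations, stimulation effects) so the full pipeline
    is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
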