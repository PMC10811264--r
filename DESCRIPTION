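Package: neckcontrol
Title: Omni-Directional Neck-Muscle Feedback Control for Head-Neck Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Feedback controllers for neck muscle activation in occupant
    simulation of evasive vehicle maneuvers. Implements a rotational
    controller driven by the axis-angle representation of head rotation and
    a translational controller driven by the angular deviation of the
    T1-to-head link, both feeding a delayed-error PID chain with saturation,
    spatial-tuning-pattern (STP) intermuscular load sharing, baseline
    activity and first-order activation dynamics. Includes construction of
    STPs from multi-experiment EMG source tables (priority merging,
    mirroring, per-direction normalization over a 26-direction grid), a
    surrogate rigid-body head-neck plant with braking and lane-change pulse
    generators, sequential response surface (SRSM) gain tuning with domain
    reduction and a saturation-duration-penalized activity constraint, and
    objective curve-rating of simulated kinematics against mean +/- SD
    reference corridors with magnitude-weighted overall scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
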