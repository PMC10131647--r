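Package: turnkin
Title: Turning-While-Walking Kinematics and Intersegmental Coordination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for turning-while-walking assessed with optical
    motion capture. Converts marker trajectories (C3D or a documented CSV
    dialect) into body-segment yaw signals via per-frame rigid Procrustes
    fits, detects 180-degree turns per segment with mean-shift change-point
    detection, extracts gait events from heel/toe marker vertical velocities,
    and computes general (turn duration, steps while turning), segmental
    (peak angular velocity) and intersegmental (relative turning onset
    latency, maximum intersegmental angle) measures, dual-task cost, and
    mixed group-by-condition ANOVAs with a gait-speed covariate,
    Greenhouse-Geisser correction and Bonferroni post hocs. Includes a
    synthetic-trial generator with exact ground truth for validating the
    detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
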