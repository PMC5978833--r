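Package: shoulderom
Title: Shoulder 3D Reachable-Workspace and Deltoid EMG Assessment from Wearable IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Converts wearable inertial-measurement-unit (IMU) quaternion streams into
    gimbal-lock-free spherical arm coordinates (azimuth and elevation relative to a
    neutral hanging-arm reference), extracts the maximal voluntary reachable-workspace
    envelope of the shoulder with its surface area in square degrees, partitions the
    workspace into six range-of-motion regions, and overlays MVC-normalized surface-EMG
    intensity of the three deltoid sections across the workspace. Includes a simulator
    that emulates the measurement hardware: protocol-compliant expanding arm circuits,
    a servo-driven gimbal rig with known pitch/yaw schedules for sensor validation, and
    an elevation-dependent EMG surrogate. Trial and cohort reporting reproduce standard
    repeatability statistics (coefficient of variation, per-plane maxima, group means).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    zoo,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
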