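Package: kinfilt
Title: Model-Based Kinematic Filtering of Markerless Motion-Capture Skeleton Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates and reinforces noisy upper-body skeleton streams from
    RGB-D trackers (OpenNI/NITE-style 3D joint centroids with confidence
    values). Provides an articulated upper-body model with anthropometric
    limb proportions, analytic arm inverse kinematics with joint limits and
    reachability clamping, two-level capsule self-collision detection,
    confidence gating and validated cubic-spline trajectory interpolation,
    online limb-length learning with a time-varying-coefficient running
    average, rigid-transform calibration and cross-correlation temporal
    alignment between capture systems, and a synthetic tracker emulator that
    reproduces documented depth-tracker failure modes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
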