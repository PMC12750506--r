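Package: strideline
Title: Groundline-Referenced Stride Symmetry Analysis for Equine Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markerless gait analysis for trotting horses from 2D keypoint
    trajectories. Estimates a per-frame dynamic groundline from hoof
    keypoints, derives calibrated vertical displacement signals (VDS) for
    the eye, withers and croup, segments strides and computes the Maxdiff
    and Mindiff symmetry metrics, and quantifies agreement between camera
    conditions with Bland-Altman statistics. Includes a kinematic simulator
    of a horse trotting on a treadmill observed through configurable pinhole
    cameras (static, oblique and handheld), so the whole pipeline can be
    exercised and validated without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
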