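Package: skikin
Title: Joint Kinematics of Alpine Ski Turns from Wearable Sensors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for knee and hip kinematics recorded during
    alpine ski runs with electrogoniometers and a trunk accelerometer.
    Provides zero-phase Butterworth low-pass filtering with spectral
    characterization, turn-switch detection from the resultant acceleration,
    segmentation of runs into inside-leg/outside-leg half-cycles,
    classification of samples into quasi-isometric, eccentric and concentric
    contraction modes by an angular-velocity threshold (and the legacy
    extrema-based bipartition), per-cycle phase metrics, angle-by-velocity
    density grids, and mixed linear models with Tukey-adjusted contrasts and
    mixed-model effect sizes. A synthetic ski-run generator with exported
    ground truth makes every stage testable without athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
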