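Package: fabricmotion
Title: Comparing Clothing-Mounted and Body-Worn Accelerometer Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for paired tri-axial accelerometer
    recordings from a body-worn sensor and a sensor mounted on the garment
    over the same site.  Provides jump/tap synchronisation-marker
    detection, inter-sensor time-lag estimation and correction by
    normalised cross-correlation, gravity alignment via the Rodrigues
    rotation, per-activity Pearson correlation analysis under five
    cumulative preprocessing variants, and a threshold decision-tree
    activity classifier with body-versus-clothing agreement confusion
    matrices.  Includes a synthetic paired-stream generator emulating
    gait oscillation, posture changes, fabric swing and marker spikes so
    the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
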