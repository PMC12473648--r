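Package: gloriafall
Title: Fall Detection from Video by Direct Reconstruction of Global Motion Parameters
Version: 0.1.0
Authors@R: person("GATE", "Vision Lab", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Detects human falls in video without computing a dense optical-flow
    field. For each consecutive frame pair the six amplitudes of the global
    linear non-homogeneous motion group (two translations, dilation, rotation,
    two shears) are reconstructed directly by a generator-basis least-squares
    solve on the brightness-constancy constraint (the GLORIA approach). The
    per-pair 6-vectors are assembled into 6 x 150 motion windows and classified
    as fall / no-fall by a compact convolutional network or a hybrid
    CNN-BiLSTM, both implemented natively. Includes seeded synthetic scene and
    motion-window generators for fully self-contained testing, confusion-matrix
    and ROC/AUC evaluation, and a command-line pipeline for extraction,
    training, detection and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    yaml,
    digest,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
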