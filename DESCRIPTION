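Package: historeg
Title: Multi-Stage Registration of Serial Histology to In Vivo MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to restore the spatial relationship between 2D histology
    sections and 3D in vivo MR imaging through the intermediate imaging
    stages of a destructive histopathology workflow: 2D diffeomorphic
    histology-to-blockface registration, currents-based sequential tissue
    block reconstruction to an ex vivo surface, ex-vivo-to-in-vivo
    feature-surface registration, transform composition, volumetric
    histology label construction, and spatial biomarker evaluation
    (precision, recall, Dice, Hausdorff distance, target registration
    error).  Includes a synthetic destructive-histopathology phantom with
    known ground-truth deformations so every restoring stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
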