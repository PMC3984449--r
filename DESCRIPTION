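Package: ctlesion
Title: Automated Delineation of Stroke Lesions from Brain CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated delineation of ischemic and hemorrhagic stroke
    lesions from non-contrast brain CT. A patient scan is stripped of non-head
    signal, rigidly coregistered to a CT template, intensity-transformed with an
    invertible piecewise map that enhances the CSF/parenchyma contrast, warped to
    template space in two steps (12-parameter affine, then a deformable
    registration of skull-stripped images), resliced and smoothed, and finally
    compared voxel-by-voxel against a normative model built from control scans
    using the Crawford-Howell t-test for single case versus control-group
    comparisons. Thresholding the t-score map yields a ternary lesion map
    (-1 ischemia, 0 normal, +1 hemorrhage) in template and native space.
    Includes a synthetic head-phantom generator with spherical lesion injection,
    Dice/sensitivity/PPV evaluation with parameter sweeps, and voxel-based
    lesion-symptom mapping (VLSM) with max-statistic permutation thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
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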