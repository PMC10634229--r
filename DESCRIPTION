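Package: striothal
Title: Compartment-Specific Striato-Pallido-Thalamic Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Parcellates the striatum into striosome-like and matrix-like
    voxels from paired connectivity probability maps, localizes
    compartment-specific striato-pallido-thalamic streamline bundles, and
    quantifies per-thalamic-nucleus compartment bias with the associated
    quality control and statistics (equal-volume mask selection, waypoint
    normalization, Dice overlap at graded stringency, suprathreshold
    bias counting, hemispheric laterality tests).  Ships a synthetic
    volumetric cohort generator with known ground truth so the full
    pipeline is testable end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
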