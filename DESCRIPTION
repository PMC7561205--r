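Package: ctcompat
Title: Compatibility Mapping of Lung-Nodule Radiomic Features Across CT
    Reconstruction Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates solid lung nodules imaged under a grid of CT
    acquisition and reconstruction conditions (radiation dose, reconstruction
    kernel, slice thickness), extracts 28 histogram, co-occurrence,
    run-length, gray-level-dependence and gray-tone-difference texture
    features per region-of-interest slice, and quantifies the reproducibility
    of nodule volumetry and radiomics across conditions with normalized
    volumes, two-tailed t compatibility tests, and condition-by-condition
    compatibility-ratio maps. Also runs on user-supplied NIfTI volumes and
    masks laid out with per-thickness reference ROIs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
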