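Package: gammaspc
Title: Gamma-Index Dose Comparison and Statistical Process Control for
    Patient-Specific Radiotherapy QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for commissioning and monitoring independent dose
    calculations in stereotactic radiotherapy QA: a multi-dimensional
    (1D/2D/3D) gamma-index engine with global or local dose normalization,
    dose cutoff and a brute-force verification oracle; beam-model
    validation statistics (output-factor relative errors, 1D gamma
    comparison of depth-dose curves and off-centre ratios); individuals
    and moving-range statistical-process-control charts with action
    levels; dose-grid I/O (scan CSV, portable JSON grids, minimal DICOM
    RT Dose); and synthetic-data generators with analytic ground truth
    for end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
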