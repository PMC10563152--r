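Package: apobdetect
Title: Label-Free Detection and Profiling of Apoptotic Bodies in Nanowell
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and profiling apoptotic bodies (ApoBDs) in
    multi-channel time-lapse images of single nanowells from cell-cell
    interaction (TIMING-style) cytotoxicity assays. Provides classical
    blob-based ApoBD detection (scale-normalised Laplacian-of-Gaussian with
    adaptive flood-fill segmentation and shape filtering), automatic
    weak-label segmentation-dataset generation, per-frame ApoBD presence
    classification with nanowell-grouped cross-validation, onset-of-apoptosis
    calling from consecutive-frame constraints, ApoBD-to-cell association by
    least average distance with majority voting, effector-target contact
    detection, and Annexin-V validity and localization analyses based on mask
    overlap (IoU) and Pearson correlation. Includes a synthetic nanowell video
    simulator with full ground truth so that every stage is testable without
    real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
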