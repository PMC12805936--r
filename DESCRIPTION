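Package: ctcscreen
Title: Surface-Marker Screening for Live Circulating Tumor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discovering cell-surface markers that detect
    live circulating tumor cells (CTCs) in blood. Implements single-cell RNA-seq
    quality control (uniquely-mapped-read and mitochondrial-fraction filters),
    median-of-ratios size-factor normalization, a multi-stage candidate-marker
    filter cascade that subtracts blood-expressed genes and selects highly
    expressed, well-covered, protein-coding plasma-membrane genes, detection
    statistics for marker panels, and quantification rules for
    immunofluorescence images (nuclear-mask segmentation, mean-gray-value
    classification, percent-positive staining) and flow-cytometry-style event
    gating. A synthetic-data module generates count matrices, reference tables,
    images and event tables with ground truth so every stage can be exercised
    and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
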