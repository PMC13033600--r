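Package: tilscope
Title: Automated Annotation of Tumor-Infiltrating Lymphocytes in H&E Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated, lightweight pipeline for annotating hematoxylin and
    eosin (H&E) stained lung adenocarcinoma images: deterministic tissue-contour
    segmentation (Roberts edges, Otsu thresholding, morphological closing and an
    HSV stain gate), a small nested-U convolutional network for tumor-parenchyma
    segmentation trained with a weighted cross-entropy plus Dice composite loss,
    a compact single-stage anchor-based detector for lymphocytes (CIoU box
    regression, multi-scale heads, non-maximum suppression), stromal TILs
    counting with per-high-power-field grading, and the full inter-rater
    agreement battery (ICC, Cohen's and Fleiss' kappa, Bland-Altman). Includes a
    seeded synthetic-histology generator with exact ground truth so every stage
    is testable without slide archives, QuPath-dialect GeoJSON annotation I/O,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
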