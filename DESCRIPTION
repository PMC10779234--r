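Package: leafgrade
Title: Automated Leaf-Damage Annotation and Five-Level Severity Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying foliar damage (lesions and defoliation) in
    single-leaf photographs on near-uniform mat backgrounds. The pipeline
    segments the leaf blade by automatic (Otsu) thresholding, extracts the
    blade outline and interior damage contours, measures polygon areas with
    the Shoelace formula, converts defect areas into damage percentages, and
    grades each defect on a five-level severity scale. Annotations are
    written as PASCAL VOC XML or YOLO text labels, and a dataset builder
    provides uniform resizing, train/validation/test splitting, mosaic and
    basic augmentations. A synthetic-leaf generator with analytically known
    ground truth makes every stage testable, and an evaluation module
    implements IoU, GIoU, precision/recall/F1, average precision, mAP,
    background-aware confusion matrices, F1-confidence curves, and a
    reference grid-cell detection loss.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    mgcv,
    png,
    xml2,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
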