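Package: colposeg
Title: Annotation Processing, Dataset Curation and Evaluation for
    Colposcopy Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and evaluating multi-class segmentation
    datasets from expert-annotated colposcopy images.  Reads CVAT for
    Images 1.1 XML and COCO 1.0 JSON annotation exports, decodes and
    encodes run-length-encoded brush masks, converts binary masks into
    model-ready simple polygons (hierarchical contour extraction,
    simplification, minimum-area filtering, donut-shape merging via
    connector bridges, connected-component splitting, 0-1 coordinate
    normalization), assembles per-class datasets with background-image
    injection and seeded train/validation/test splits (image- or
    patient-level), and evaluates predictions with pixel-level Dice, IoU,
    precision and recall, instance-level mask mAP50-95 and F1, and the
    composite tuning objective 0.7 * F1 + 0.3 * mAP50-95.  A seeded
    synthetic-scene generator provides ground truth and perturbed
    predictions so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    xml2,
    yaml,
    optparse,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
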