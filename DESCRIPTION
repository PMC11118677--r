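Package: patchROI
Title: Patch-Based Region-of-Interest Detection in Melanocytic Tumor
    Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Weakly-supervised region-of-interest (ROI) detection for
    hematoxylin-and-eosin whole-slide images of melanocytic skin tumors
    (melanoma versus nevus). Slides are tiled into non-overlapping
    256x256 patches, a three-class patch classifier (melanoma, nevus,
    other) is trained from partial pathologist annotations, slides are
    classified by majority vote over patch predictions, and the ROI is
    selected as the top n-beta patches ranked by the winning-class
    score, where beta is the annotated ratio. Includes Aperio
    ImageScope annotation XML input/output, HSV tissue detection,
    Reinhard-style color normalization, patch-grid intersection-over-
    union evaluation, OPTICS-based boundary visualization, and a
    deterministic synthetic slide generator with partial annotations
    and full ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    xml2,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'annotations-io.R'
    'preprocessing.R'
    'patching.R'
    'features.R'
    'classifier.R'
    'detection.R'
    'optics.R'
    'visualization.R'
    'synthetic.R'
    'config.R'
    'pipeline.R'
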