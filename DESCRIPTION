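Package: oiearr
Title: Quantification and Grading of Orthodontically Induced External Apical
    Root Resorption from Panoramic Radiograph Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify orthodontically induced external apical root
    resorption (OIEARR) of the maxillary incisors from landmark (pose) or
    bounding-box (detection) annotations of paired pre- and post-treatment
    panoramic radiographs. Implements YOLO-format label parsing and writing,
    crown-referenced magnification correction, percentage root resorption,
    Sharpe-style 0-3 grading with configurable thresholds, a seeded synthetic
    cohort generator with known ground truth, and an evaluation suite:
    multiclass confusion matrices, one-vs-rest metrics and ROC-AUC for
    label-only classifiers, Grade-0-referenced measurement error, two-way
    random-effects intraclass correlation, and exact binomial power analysis
    for sample-size planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
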