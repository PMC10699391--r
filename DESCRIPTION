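Package: gimkit
Title: Graphical Item Maps for Rasch-Calibrated Assessment Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibrates dichotomous exam items with the Rasch model by
    conditional maximum likelihood (elementary symmetric functions),
    estimates candidate abilities with Warm's weighted likelihood
    estimator, and constructs per-candidate graphical item maps (GIMs):
    items are arranged in subject-cluster columns, placed vertically by
    difficulty in logits, and split left/right by correctness, with
    ability and pass-standard reference lines, quadrant assignment and
    per-subject strength/weakness flags. Includes a partial-credit
    category mapping, a classical-test-theory facility-axis variant with
    practitioner-level classification, deterministic SVG and plain-text
    renderers, and a seeded response simulator for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
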