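Package: airwayCT
Title: Upper-Airway CT Segmentation and Collapse Analysis by Iterative
    Single-Threshold Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying upper-airway collapsibility from
    respiratory-phase CT volumes. Implements iterative single-threshold
    (isodata-style) segmentation with morphological erosion cleanup and
    connected-component lumen extraction, anatomical partitioning of the
    airway into nasopharyngeal, posterior palatal, retrolingual and
    laryngopharyngeal regions, per-region cross-sectional area and
    collapse-degree measurement across respiratory phases, multi-task
    detection loss functions (cross-entropy plus smooth-L1), and
    two-sample cohort comparison statistics. Ships a synthetic phantom
    and cohort generator for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
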