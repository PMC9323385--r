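Package: CBCTeeth
Title: Hierarchical Teeth Detection on Axial CBCT Slice Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and labels individual teeth on stacks of axial cone beam
    computed tomography (CBCT) slices. Slices are classified into jaw regions
    with an anti-noise switch state machine, teeth are detected hierarchically
    (main dental area, then five anatomical blocks per jaw), block boxes are
    subdivided into FDI-numbered per-tooth bounding boxes by proportion
    formulas with calibratable lambda coefficients, and key-slice boxes are
    propagated across the stack. Includes detection metrics (precision,
    recall, F1, mean average precision, object inclusion ratio), readers and
    writers for DICOM series, Pascal VOC XML and JSON annotations, and a
    deterministic synthetic dental phantom generator with full ground truth
    for end-to-end testing without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
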