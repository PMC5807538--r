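Package: cometscore
Title: Automated Scoring of Comet Assay (Single-Cell Gel Electrophoresis) Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects, classifies and quantifies comets in single-focal-plane
    gel-electrophoresis well images such as those produced by micro-patterned
    comet-assay arrays. Candidate objects are segmented with a scanning-box
    adaptive threshold, screened by rule-based plausibility checks (size,
    orientation, shape, symmetry), background-corrected with a fitted bilinear
    surface, and measured on the axial intensity profile to yield percent tail
    DNA, tail length, tail moment, tail area and tail intensity. Includes a
    synthetic-comet generator with analytically known ground truth for
    validating the measurement chain, plate-level aggregation (per-well
    summaries, edge-effect reports, pooled-variance t-tests, coefficient of
    variation) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    pracma,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
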