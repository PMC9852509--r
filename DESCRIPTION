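Package: htoplan
Title: Concentric-Circle Preoperative Planning for Medial Open-Wedge
    High Tibial Osteotomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional geometry and statistics for preoperative
    planning of medial open-wedge high tibial osteotomy (HTO) from
    digitized standing whole-leg radiographs.  Implements the
    concentric-circle (Miniaci-style) construction of the correction
    angle and opening gap, the standard frontal-plane alignment
    measures (weight-bearing-line ratio, mechanical femorotibial
    angle, medial proximal tibial angle), pixel-to-millimetre
    calibration and a versioned JSON landmark format, a synthetic-limb
    generator with a landmark-noise model, a virtual osteotomy that
    verifies a plan by rigid closure about the lateral hinge, and
    cohort reporting statistics (paired t, intraclass correlation,
    correction classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
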