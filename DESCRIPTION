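Package: atpTCA
Title: Analysis of ATP-Based Tumour Chemosensitivity Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for ATP-based tumour chemosensitivity (ATP-TCA) microplate
    assays. Converts raw 96-well luminescence counts into percentage tumour
    growth inhibition using medium-only (MO) and maximum-inhibitor (MI)
    plate controls, with replicate coefficient-of-variance quality control;
    estimates IC50 and IC90 by log-linear interpolation or Hill-curve
    fitting; computes the IndexSUM sensitivity statistic over six doubling
    dilutions; and scores fixed-ratio drug combinations with Chou-Talalay
    combination indices at 50% and 90% effect, classified as synergy,
    additivity or antagonism. Includes a synthetic plate simulator with
    Loewe-additive combination ground truth, and a preset isogenic
    MCF10a-style cell-line panel, so every analysis stage can be validated
    against known dose-response parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
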