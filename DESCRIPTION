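Package: linacqa
Title: Quantitative Analyses for Linac SRS/SBRT Commissioning and QA
Version: 0.1.0
Authors@R:
    person("QA", "Physics", email = "qa.physics@example.org", role = c("aut", "cre"))
Description: Image and dose analyses used when commissioning a linear
    accelerator for stereotactic radiosurgery and stereotactic body
    radiation therapy: Winston-Lutz isocentricity from portal images,
    picket-fence and star-shot multi-leaf collimator tests, dynamic
    leaf gap fitting from sweeping-gap dose series, small-field
    output-factor daisy-chaining, percent-depth-dose and lateral
    profile metrics, relative modulation transfer functions from
    line-pair phantoms, image-guidance localization statistics with
    rigid couch-rotation verification, and end-to-end dosimetric
    verification with film conversion and 2D gamma analysis. Seeded
    synthetic phantom-data generators with ground-truth manifests
    replace machine measurements for testing.
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
    withr
Config/testthat/edition: 3
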