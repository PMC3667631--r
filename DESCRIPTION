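Package: mucinscreen
Title: Hit Calling for Plate-Based RNAi Secretion Screens
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage hit calling for high-throughput siRNA screens read
    out by a per-well secretion assay (e.g. chemiluminescent detection of
    secreted mucin). Implements per-plate B-score normalization by Tukey
    two-way median polish with MAD scaling, rank-product aggregation of
    replicate rankings with a permutation null, primary hit selection on
    the median B-score, a z-score validation stage with mock-control
    2-SD cutoffs, annotation and expression triage filters, readout
    normalization utilities, a synthetic plate-screen generator with
    ground truth for benchmarking, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
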