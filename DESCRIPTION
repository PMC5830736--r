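Package: songdyad
Title: Acoustic and Spatial Interaction Analysis for Humpback Whale Singer Dyads
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies countersinging interactions between simultaneously
    singing humpback whales. Computes phrase-type switching rates and
    relative song evenness (normalized Shannon entropy) over fixed analysis
    windows, tests phrase-type overlap between two singers against a Monte
    Carlo time-shift null distribution, and analyses singer movement
    (separation distances, meander ratios) against spatial null
    distributions built by superimposing tracks of solo singers. Includes a
    synthetic-data generator for cyclical eventual-variety song sequences
    and correlated-random-walk singer tracks, so the whole pipeline is
    testable without acoustic recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
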