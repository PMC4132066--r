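Package: divesync
Title: At-Sea Association and Synchronous-Diving Analysis for
    GPS/TDR-Tracked Central-Place Foraging Seabirds
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting at-sea associations between simultaneously
    GPS- and time-depth-recorder (TDR) tracked central-place foraging
    seabirds.  Provides speed filtering and foraging-trip segmentation of
    GPS tracks, zero-offset correction and dive detection from depth
    records, bout analysis via a two-process exponential-mixture
    bout-ending criterion fitted by maximum likelihood, pairwise
    spatiotemporal association-episode detection with rafting exclusion,
    synchronous-dive detection, per-trip association-type classification,
    Mantel and Mann-Whitney group statistics, and a seeded synthetic
    deployment generator with ground-truth labels for end-to-end testing.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
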