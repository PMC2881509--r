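Package: overlapEnrich
Title: Gene-List Overlap Significance, Hypergeometric Enrichment, and
    Two-Group Upregulation Lists
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds upregulated gene lists from two-group expression
    matrices with one-sided t-tests, scores gene-list intersections
    against a hypergeometric null over a user-supplied gene universe,
    scans query lists against GMT gene-set collections by overlap
    p-value, and cross-tabulates curated gene panels against reference
    lists. Ships a synthetic two-group expression simulator with planted
    upregulated genes and paired studies sharing a planted up-module, so
    every stage is testable without external data. Includes a
    command-line interface covering the full simulate - test - list -
    overlap - enrich - panel pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
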