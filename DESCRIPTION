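Package: rlitools
Title: Red List Index Toolkit for Backcasted Species Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing IUCN Red List assessment tables with
    backcasted category timelines, in the style of the Global Amphibian
    Assessment. Implements genuine-change accounting against a declared
    change ledger, the Red List Index with Possibly Extinct weighting and
    Data Deficient exclusion, disaggregation by realm, taxonomic order and
    breeding strategy, threatened-fraction uncertainty bounds, IUCN
    threat-classification code grouping and tallies, equal-area grid
    summaries of richness and dominant deterioration drivers, and a
    synthetic-assessment generator for testing pipelines at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
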