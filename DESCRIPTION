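Package: ReproScreen
Title: Analysis of a High-Throughput C. elegans Reproductive Toxicity Screen
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of a high-throughput Caenorhabditis
    elegans aneuploidy-reporter ("Green Eggs and HIM") chemical screen:
    well-level quality control, GFP-positive worm ratios, per-concentration
    Z-score normalization and high/low chemical classification, embryonic
    lethality confirmation statistics (Welch and Brown-Forsythe ANOVA with
    control-wise multiple comparisons), and integration with ToxCast-style
    in vitro assay tables (bioactivity ratios, log10 AC50 handling, and
    Fisher-exact target-family enrichment with FDR control). A seeded
    synthetic-data generator emulates the structure of the screen so the
    full pipeline is testable without external data; the published summary
    tables of the 133-chemical screen are included as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
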