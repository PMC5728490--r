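Package: phowaves
Title: Growth Kinetics, Transcription Waves, and Competition Fitness
    under Phosphate Starvation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for budding-yeast phosphate-starvation
    experiments: growth-rate estimation from OD600 time series via
    smoothing-spline fits with density-matched normalization against a
    rich-medium reference, UMI-corrected 3'-tag RNA-seq quantification
    with ambiguous-read allocation, detection of the two sequential
    transcription waves of the PHO regulon by k-means clustering of
    time-point correlation matrices, rule-based classification of
    Pho4-regulated genes, and competitive-fitness estimation from
    flow-cytometry event streams with acquisition-carryover filtering.
    Includes a seeded synthetic-data generator that emulates the
    statistical structure of phosphate-limited cultures so that every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
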