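Package: crtcore
Title: Core Microbiome and Conditionally Rare Taxa in Temporal ASV Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for temporal 16S rRNA amplicon sequence variant
    (ASV) count tables from repeatedly sampled freshwater sites. Implements
    rarefaction to a common depth, abundance-occupancy ranking with core
    selection by marginal contribution to whole-community Bray-Curtis
    beta-diversity, detection of conditionally rare taxa via the coefficient
    of bimodality, per-date decomposition of Bray-Curtis dissimilarity into
    subcommunity contributions, temporal community stability (constancy), and
    Spearman rank correlations with environmental covariates. Includes a
    synthetic multi-site, multi-year community generator with planted core,
    conditionally rare, and background taxa for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    e1071,
    biomformat,
    jsonlite
Config/testthat/edition: 3
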