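Package: mirfunnel
Title: Integrative miRNA Candidate Discovery from Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for nominating candidate microRNA (miRNA)
    regulators from bulk sequencing count data. Provides a minimal negative-
    binomial differential-expression engine (pairwise Wald-style tests, a
    likelihood-ratio screen, median-of-ratios normalization, a variance-
    stabilizing log transform and batch removal), expression-module clustering
    across genotypes, a Monte-Carlo target-site enrichment statistic built on
    canonical seed-match scanning (8mer, 7mer-m8, 7mer-1A) with species-
    conservation filters, candidate-selection funnels for model-organism and
    tumor/normal arms (including mutation/copy-number genotype binning and a
    pan-cancer summary), and a joint steady-state/nascent-transcription
    classifier of post-transcriptional regulation. A synthetic-data module
    generates negative-binomial count matrices, 3'UTR sequences with planted
    seed sites, and mutation tables with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    limma,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
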