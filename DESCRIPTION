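Package: riceseedtx
Title: Seed-Development Transcriptome Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled pipeline for microarray-era transcriptome
    analysis of developing rice seed: presence/absence detection calls and
    expressed-gene logic, quantile normalization and replicate quality control,
    empirical-Bayes moderated contrasts for tissue-predominant expression,
    one-way ANOVA time-course tests, cold-response differential expression and
    cross-dataset trend concordance, chi-square category over-representation
    with Benjamini-Hochberg FDR, strand-aware promoter extraction and IUPAC
    cis-element enrichment against a genome background, and transcription
    factor guilt-by-association annotation over a co-expression compendium
    with bipartite network export. A synthetic-data module generates
    compendia, cold experiments, co-expression collections and promoter sets
    with planted ground truth so every stage can be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
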