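Package: chillseq
Title: Chilling Response and Acclimation Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing chilling response and
    chilling acclimation in plant transcriptomes and microRNAomes from tag
    count data across four temperature conditions (normal control, chilling
    acclimation, chilling after acclimation, and chilling shock). Implements
    rule-based expressed and differential-expression calling on raw counts
    (counts-per-million thresholds, upper-quartile normalization, fold-change
    and on/off criteria), multi-condition expression-trajectory (reversal)
    analysis, penalty-scored plant miRNA target prediction with seed-region
    and G:U wobble weighting, miRNA-mRNA anti-correlation integration,
    hypergeometric GO term enrichment with Benjamini-Hochberg FDR, small-RNA
    adaptor trimming and read qualification, and a synthetic-data generator
    with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
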