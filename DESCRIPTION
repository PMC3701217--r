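Package: medipdmr
Title: Differential DNA Methylation and Small RNA Integration for MeDIP
    Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for differential DNA methylation
    analysis of two-colour MeDIP (methylated-DNA immunoprecipitation)
    promoter tiling arrays and its integration with small noncoding RNA
    expression. Implements median-centring quantile normalisation and
    running-mean smoothing of probe-level log2(MeDIP/Input) tracks, a
    sliding-window rank-sum peak finder, the M-prime differential
    enrichment statistic with replicate-variability (CV) and median-ratio
    peak filters, PeakScore-based hierarchical clustering (UPGMA), per
    feature ANOVA/fold-change differential expression, delta-delta-Ct qPCR
    quantitation, inverse miRNA-target pairing, promoter methylation and
    expression concordance, imprinted-region interval mapping, and a
    permutation test for region enrichment. A synthetic-data generator
    plants differentially methylated regions and inverse miRNA-target
    pairs with known truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
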