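Package: coldatlas
Title: Organ-Specific Cold Stress Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of organ-resolved cold-stress RNA-seq experiments in
    plants.  Provides a negative-binomial count simulator with planted
    stress effects, organ-specific expression patterns and transcription
    factor regulons; a moderated negative-binomial Wald test for
    stress-versus-control contrasts with median-of-ratios normalisation;
    cross-organ Down/Up/Mix response classification with commonality
    counting and direction concordance against signed reference lists;
    Shannon-entropy expression-pattern-width and pairwise DE Score
    specificity metrics over a transcriptome map; Fisher exact gene-set
    enrichment with Benjamini-Hochberg false discovery rate control; and
    replicate-correlation and hierarchical-clustering quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
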