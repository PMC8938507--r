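Package: regensc
Title: Injury-Induced Reprogramming Analysis for Plate-Based Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for plate-based (CEL-seq2-style)
    single-cell RNA-seq studies of intestinal crypt regeneration: UMI
    demultiplexing and gene counting from paired FASTQ, quality-control
    filtering, normalization, variable-gene selection, PCA with a centroid
    batch adjustment, SNN-graph Louvain clustering and seeded t-SNE embedding,
    a min-max-scaled gene-signature score rescaled to average absolute
    expression, a transcriptional-diversity stemness score, Wilcoxon
    marker and differential-expression tables, and the group-comparison
    statistics used in regeneration studies (Steel-Dwass all-pairs,
    Tukey-Kramer, crypt positivity fractions). Includes a negative-binomial
    count and FASTQ simulator with planted ground truth emulating a 96-well
    two-condition, two-gate, two-replicate design, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
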