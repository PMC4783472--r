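Package: trioscope
Title: Joint Copy-Number, Methylome and Transcriptome Analysis of Single Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for single-cell triple-omics data in which one cell yields a
    reduced-representation bisulfite (RRBS) methylome, a read-depth copy-number
    profile, and a transcriptome. Implements in-silico MspI digestion with
    bisulfite-space mappability flagging, read-depth copy-number inference with
    control normalization and hidden-Markov integer fitting, expression-based
    relative copy-number estimation by positional moving averages,
    methylation-expression correlation and metagene profiles, weighted
    cell-to-cell methylation variance ranking, differentially methylated
    CpG-island calling from pooled counts, and a synthetic triple-omics
    simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
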