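Package: coregscan
Title: Conserved Promoter Framework Discovery and Co-Regulated Gene Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for promoter-level "promotology" analysis: derive and
    quality-filter ortholog promoter sets, vet them by distance-based
    phylogenetics (neighbor-joining and UPGMA with bootstrap), scan sequences
    with position weight matrices and degenerate IUPAC motifs using
    information-weighted core/matrix similarity scores, discover ordered
    motif combinations (frameworks) conserved across a quorum of promoters,
    turn frameworks into screenable regulatory models with inter-element
    distance constraints, map model hits from clones to chromosomal
    coordinates with strand/orientation-aware rules, select candidate
    co-regulated genes by TSS distance and overlap filters, and validate
    candidates against expression matrices (quantile normalization, Wilcoxon
    rank-sum tests, fold-change flagging). Includes generators for
    ground-truthed synthetic promoter sets, toy genomes and expression
    matrices so every pipeline stage can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
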