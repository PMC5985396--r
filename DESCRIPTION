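Package: arasig
Title: Epigenetic Signatures at Androgen-Receptor-Associated lincRNA Loci
Version: 0.1.0
Authors@R:
    person("arasig", "maintainers", email = "arasig@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit that distinguishes the genomic
    loci of androgen-receptor-associated lincRNAs (ARA-lincRNAs) from
    non-associated control lincRNAs (NonA-lincRNAs). Implements
    negative-binomial enrichment testing of RIP-seq counts with
    Benjamini-Hochberg FDR control, construction of a matched NonA control
    set, closest-TSS neighbor pairing, a local-background Poisson peak
    caller for ChIP-seq tracks, TSS-window epigenetic feature encoding, a
    random-forest classifier with a label-shuffle Gini-importance null,
    topologically-associating-domain (TAD) profiling, enhancer-signature
    statistics, and a synthetic study generator with planted ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
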