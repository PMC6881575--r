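Package: cncnet
Title: Coding-Noncoding Co-Expression and ceRNA Network Analysis for
    Microarray Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-quantification analysis of two-group microarray
    expression profiles of mRNAs, long noncoding RNAs (lncRNAs) and
    circular RNAs (circRNAs): differential expression with fold-change,
    Student t-test and Benjamini-Hochberg FDR filtering; positional
    classification of lncRNAs relative to protein-coding genes
    (six-category scheme with multi-label Venn counts); cis-candidate
    gene discovery within a genomic window; coding-noncoding (CNC)
    co-expression networks from thresholded Pearson correlations;
    trans-regulatory lncRNA-TF-mRNA networks from position-weight-matrix
    promoter scanning with exact E-value tails and hypergeometric
    TF-target enrichment; competing endogenous RNA (ceRNA) networks from
    canonical miRNA seed-site matching (6mer, 7mer-A1, 7mer-m8, 8mer,
    with back-splice-junction wraparound for circRNAs); and GO/KEGG-style
    term over-representation. Ships a synthetic-data generator that
    plants known differential expression, co-expressed pairs, genomic
    configurations, motif and seed sites, and an enriched term, so every
    stage is verifiable against ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
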