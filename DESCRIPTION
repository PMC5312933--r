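Package: borderchip
Title: Simulation and Classification of Insulator-Associated ChIP-Seq
    Binding Sites at Heterochromatin Borders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the downstream analysis of ChIP-seq binding maps of
    boundary-associated chromatin factors in Drosophila-like genomes.
    Implements fixed-width peak calling against an input control, broad
    heterochromatin (HP1a-type) domain segmentation, replicate-consensus
    selection, combinatorial overlap of peaks with insulator-protein
    reference sets (gypsy-like classification), heterochromatin-adjacency
    classification of peaks (class 1 borders versus class 2), position
    weight matrix motif scanning, knockdown fold-change quantification with
    Wilcoxon rank tests, repeat-consensus enrichment (RPKM, log2 fold
    change), anchor-centered composite profiles and heatmap matrices, peak
    annotation to genomic landmarks and expression-linkage comparisons. A
    truth-tracked synthetic data generator produces toy genomes, annotations
    and fragment-based ChIP/input/knockdown tag samples so that every stage
    is testable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
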