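Package: atacreg
Title: Condition-Specific Chromatin Accessibility and Regulatory Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Integrative analysis of two-condition ATAC-seq experiments:
    consensus and condition-specific (unique) peak calling from replicated
    peak sets, negative-binomial differential accessibility with a common
    method-of-moments dispersion, genomic annotation of peaks against
    promoter/exon/intron/intergenic space, linkage of peaks to gene bodies
    and concordantly upregulated genes, enhancer and super-enhancer overlap
    with GREAT-style basal-plus-extension gene association, position weight
    matrix scanning with exact lattice dynamic-programming p-values and
    scrambled-sequence background fold enrichment, hypergeometric gene-set
    enrichment with Benjamini-Hochberg correction, and construction of the
    bipartite transcription-factor to target-gene regulatory network.  A
    fully seeded synthetic-data generator produces genomes, gene models,
    replicated peak sets, count matrices, H3K27ac/super-enhancer tracks and
    expression tables with known ground truth so the whole pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
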