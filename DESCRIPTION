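Package: tbsmeth
Title: Targeted Bisulfite Sequencing Methylation Analysis for Gene Bodies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of targeted bisulfite sequencing (TBS) data for gene body
    methylation in clonal tree designs. Provides strand-aware CG/CHG/CHH cytosine
    context classification, Bismark-style cytosine report I/O, weighted methylation
    levels with coverage filtering, lambda spike-in conversion-rate estimation,
    capture-efficiency QC (coverage threshold curves, cross-library gene overlap,
    flanking coverage), 20-bin metagene gene-body profiles, differential methylation
    position (DMP) calling with a per-clone-pair consistency filter, PCA of
    methylation profiles, GO term over/under-representation among DMP genes, and a
    synthetic-data generator emulating a paired ortet/ramet capture experiment so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'capture_qc.R'
    'contexts.R'
    'methcalls.R'
    'diffmeth.R'
    'go_bias.R'
    'metagene.R'
    'pca.R'
    'simulate.R'
    'pipeline.R'
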