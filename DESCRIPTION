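Package: nilscan
Title: Genome-Wide Isogenicity Characterization of Near-Isogenic Line Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genome-wide genotypic characterization of
    near-isogenic line (NIL) pairs from SNP-array genotype calls:
    replicate and seed-stock concordance checks, a six-step ordered
    quality and pedigree-consistency filter, parent-of-origin allele
    encoding at polymorphic markers, genomic-distribution statistics
    (goodness-of-fit with orthogonal G decomposition, polymorphic vs
    monomorphic independence, fixed-width bin scans with
    Benjamini-Hochberg FDR control, inter-marker gap statistics),
    non-isogenic block segmentation with publication-style summary
    tables, QTL-introgression verification and linkage-drag
    measurement. A forward simulator of a marker-assisted
    residual-heterozygous-line introgression program generates
    chip-style data with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'snp-panel.R'
    'genome-model.R'
    'meiosis.R'
    'breeding.R'
    'chip.R'
    'qc.R'
    'distribution.R'
    'encode.R'
    'isogenicity.R'
    'io.R'
    'nilscan-package.R'
    'report-tables.R'
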