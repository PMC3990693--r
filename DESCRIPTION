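Package: sagscope
Title: Single-Cell Genome Completeness, Fragment Recruitment and
    Comparative Proteome Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative single-cell genomics of uncultivated
    microbes. Derives conserved single-copy gene (CSCG) marker sets from
    genome-by-family occurrence matrices and estimates completeness and
    genome size of single amplified genome (SAG) assemblies; pre-filters
    metagenome read sets (length, ambiguity, duplicate and trinucleotide
    entropy rules); recruits metagenome fragments to assemblies with an
    optimal local aligner and builds length-normalized abundance
    matrices; partitions proteomes by BLAST Score Ratio against two
    reference proteomes; calls genomic islands by the zero-recruitment
    rule with hypergeometric COG-category enrichment; and clusters SSU
    rRNA sequences into phylotypes. A seeded synthetic-data generator
    produces genomes, SAG assemblies, metagenomes, occurrence matrices
    and proteome triplets with known ground truth so the whole pipeline
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    data.table,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, Alignment, Sequencing, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bsr.R'
    'completeness.R'
    'io.R'
    'islands.R'
    'phylotype.R'
    'rng.R'
    'pipeline.R'
    'read-qc.R'
    'recruitment.R'
    'sagscope-package.R'
    'synthetic-data.R'
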