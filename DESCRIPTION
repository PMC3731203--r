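Package: riboDwell
Title: Codon-Resolution Ribosome Profiling: P-Site Calibration, Codon
    Occupancy and Queuing Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for codon-level analysis of ribosome profiling
    (Ribo-seq) libraries prepared with in-vitro polyadenylation.
    Implements footprint length determination in the presence of
    poly-A ambiguity, per-read-length P-site offset calibration from
    the start-codon metagene, pooling of 5' ends into the 28-mer
    frame, metacodon profiles and bulk codon occupancies per ribosomal
    site, a single-codon occupancy statistic with two-sample
    Kolmogorov-Smirnov comparison across strains, upstream ribosome
    queuing metaplots, ORF-windowed read counting with RPKM and
    gene-set enrichment statistics, and a seeded synthetic footprint
    simulator with known dwell-time structure that provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors
Suggests:
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: RiboSeq, Sequencing, Coverage, Transcriptomics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'reference.R'
    'process.R'
    'expression.R'
    'metacodon.R'
    'occupancy.R'
    'queuing.R'
    'synthetic.R'
    'pipeline.R'
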