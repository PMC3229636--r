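Package: duovar
Title: Two-Genome Read-Depth CNV Detection and SNP Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing two resequenced genomes against a common
    reference: windowed read-depth copy-number-variant (CNV) detection with a
    Poisson-ratio significance test, post-calling SNP quality filters,
    functional classification of SNPs against gene models with a BLOSUM62
    orthologue-conservation score, array-versus-sequencing genotype
    concordance and false-negative/false-positive rate estimation,
    calibrator-based delta-delta-Ct qPCR copy-number calling, and CNV
    gene-overlap plus Gene Ontology enrichment summaries. Includes synthetic
    data generators (read placements with planted copy-number segments, SNP
    truth sets, gene models, orthologue panels, Ct tables) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
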