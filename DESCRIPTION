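Package: gnomekit
Title: Downstream Genome-Note Analyses: Annotation Reconciliation,
    CpG Methylation Profiles, and Population-Genomic Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the downstream computations of a
    solitary-bee genome project: reconciliation of evidence-based and
    orthology-projected gene-model sets into one consolidated annotation,
    feature-stratified CpG 5mC/5hmC methylation profiling from
    base-modification pileups, filtered-variant population-genetic summaries
    (effect classes, windowed nucleotide diversity, linkage-disequilibrium
    decay, per-chromosome enrichment, inbreeding coefficients), and assembly
    quality statistics including telomere-motif detection. A seeded
    synthetic-genome module generates FASTA/GFF3/bedMethyl/VCF fixtures with
    planted truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
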