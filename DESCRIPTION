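Package: mirloci
Title: Discovery, Scoring, Annotation and Expression Profiling of miRNA
    Loci from Small RNA Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for microRNA (miRNA) locus discovery from
    multi-tissue small-RNA sequencing libraries. Reads are adapter-trimmed,
    length- and complexity-filtered and collapsed to unique sequences with
    per-library counts; unique sequences are placed on a reference genome by
    exact full-length matching with a repetitiveness cap and merged into
    candidate loci; each locus is folded into a single stem-loop with a
    purpose-built dynamic program and scored against five hairpin criteria
    (structure, precursor size, loop geometry, dominant-read placement,
    expression profile) on a 0-1300 scale with a high-confidence threshold;
    predictions are partitioned against repeat and non-coding RNA databases
    and classified structurally against gene models; expression matrices,
    family-abundance and read-length reports, average-linkage tissue
    clustering and sequencing-versus-qPCR correlation complete the profiling.
    A synthetic-data generator emits toy genomes, databases, truth tables and
    per-tissue FASTQ libraries with the statistical structure the analysis
    assumes, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
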