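Package: srnascape
Title: Genome-Wide Small RNA Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing small non-coding RNA (sRNA)
    populations from aligned small RNA sequencing reads. Clusters reads
    into sRNA-producing loci and classifies their distribution type
    (strand-specific piles versus distributed both-strand coverage),
    profiles read lengths by genomic category, classifies tRNA-derived
    fragments (tRFs) including CCA status, computes per-region RPKM,
    methylation level and expression association statistics for
    transposable elements, detects periodic sRNA coverage by
    sliding-window Fourier analysis, and evaluates candidate miRNA-like
    hairpin precursors with an empirical minimum-free-energy p-value.
    Includes a seeded synthetic-data generator that plants loci with
    known labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
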