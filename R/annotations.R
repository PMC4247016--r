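#' Load genome and annotations into an AnnotationSet
#'
#' Bundles the genome sequence, gene / repeat (TE) / non-coding RNA
#' annotations, tRNA gene models with arm sub-coordinates, and binary
#' methylation probe calls into one object used by the downstream
#' stages. Any component may be given as a file path (GFF3 or BED for
#' interval sets, TSV for the tRNA table) or as a ready-made `GRanges`.
#'
#' GFF input (1-based inclusive) and BED input (0-based half-open) are
#' both converted to the 1-based closed convention of `GRanges`, the
#' single internal convention of the package.
#'
#' @param genome A FASTA path or a [Biostrings::DNAStringSet] (optional
#'   for stages that do not need sequence).
#' @param genes,repeats,ncrnas GFF3/BED paths or `GRanges`.
#' @param trnas Path to a tRNA table (see [read_trna_table()]) or a
#'   `GRanges` with arm metadata columns.
#' @param methylation BED path or `GRanges`; the score column must carry
#'   the binary (0/1) methylated-probe call.
#' @return An object of class `AnnotationSet`: a list with elements
#'   `genome`, `genes`, `repeats`, `ncrnas`, `trnas`, `methylation`.
#' @export
load_annotations <- function(genome = NULL, genes = NULL, repeats = NULL,
                             ncrnas = NULL, trnas = NULL,
                             methylation = NULL) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- list(
    genome = genome,
    genes = import_intervals(genes),
    repeats = import_intervals(repeats),
    ncrnas = import_intervals(ncrnas),
    trnas = if (is.character(trnas)) read_trna_table(trnas) else trnas,
    methylation = import_intervals(methylation)
  )
  if (!is.null(ann$methylation)) {
    sc <- mcols(ann$methylation)$score
    if (is.null(sc)) sc <- mcols(ann$methylation)$call
    if (is.null(sc)) {
      stop_ctx("methylation probes need a 0/1 call column (BED score)")
    }
    mcols(ann$methylation)$call <- as.integer(sc)
  }
  if (!is.null(ann$trnas)) validate_trna_model(ann$trnas)
  structure(ann, class = "AnnotationSet")
}

import_intervals <- function(x) {
  if (is.null(x)) return(NULL)
  if (methods::is(x, "GRanges")) return(x)
  rtracklayer::import(x)
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet\n")
  for (nm in c("genes", "repeats", "ncrnas", "trnas", "methylation")) {
    n <- if (is.null(x[[nm]])) "absent" else length(x[[nm]])
    cat(sprintf("  %-12s %s\n", nm, n))
  }
  if (!is.null(x$genome)) {
    cat(sprintf("  genome       %d sequence(s), %s nt\n",
                length(x$genome), sum(as.numeric(width(x$genome)))))
  }
  invisible(x)
}

trna_arm_cols <- c("acceptor_start", "acceptor_end", "dloop_start",
                   "dloop_end", "anticodon_start", "anticodon_end",
                   "tloop_start", "tloop_end")

#' Read a tRNA gene table with arm sub-coordinates
#'
#' Tab-separated table with one row per tRNA gene. Required columns:
#' `trna_id, chrom, start, end, strand, isotype, anticodon` plus the
#' eight arm columns `acceptor_start/end`, `dloop_start/end`,
#' `anticodon_start/end`, `tloop_start/end`. All coordinates are 1-based
#' inclusive genomic positions; the acceptor columns describe the
#' 3'-terminal acceptor-stem span whose end is the mature 3' terminus.
#'
#' @param path TSV path.
#' @return `GRanges` with isotype, anticodon and arm metadata columns.
#' @export
read_trna_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("trna_id", "chrom", "start", "end", "strand", "isotype",
            "anticodon")
  missing_cols <- setdiff(c(need, trna_arm_cols), names(df))
  if (length(missing_cols) > 0L) {
    stop_ctx("tRNA table lacks column(s): %s (arm sub-coordinates are required for tRF classification)",
             paste(missing_cols, collapse = ", "))
  }
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr) <- df[, c("trna_id", "isotype", "anticodon", trna_arm_cols)]
  gr
}

validate_trna_model <- function(trnas) {
  missing_cols <- setdiff(c("trna_id", trna_arm_cols), names(mcols(trnas)))
  if (length(missing_cols) > 0L) {
    stop_ctx("tRNA model lacks column(s): %s (arm sub-coordinates are required for tRF classification)",
             paste(missing_cols, collapse = ", "))
  }
  invisible(trnas)
}
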