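#' Load aligned small-RNA reads
#'
#' Reads an alignment file (BAM, or the package's BED dialect) into a
#' [GenomicRanges::GRanges] of aligned reads. Each read carries its
#' sequence (when available), its multiplicity (number of genomic
#' matching locations), the derived weight `1/multiplicity`, a library
#' label, and a flag for reads outside the configured length bounds.
#'
#' The BED dialect is `chrom start end name multiplicity strand [sequence]`
#' with 0-based half-open coordinates; the fifth (score) column holds the
#' multiplicity and defaults to 1 when missing, zero or `NA`. For BAM
#' input the multiplicity is taken from the `NH` tag when present.
#'
#' Reads whose length falls outside `[min_len, max_len]` are returned
#' with `flagged = TRUE` rather than dropped; downstream functions
#' exclude flagged reads by default.
#'
#' @param path Path to a BAM or BED file.
#' @param library_label Library (condition) label attached to every read.
#' @param format `"auto"` (by extension), `"bed"` or `"bam"`.
#' @param min_len,max_len Inclusive read-length bounds of the size
#'   selection (defaults 18 and 36 nt).
#' @param genome Optional [Biostrings::DNAStringSet] (or character vector
#'   of chromosome names); records on unknown chromosomes raise an error
#'   listing the genome's names.
#' @return A `GRanges` with metadata columns `seq`, `multiplicity`,
#'   `weight`, `library`, `flagged`.
#' @export
load_alignments <- function(path, library_label = "lib1",
                            format = c("auto", "bed", "bam"),
                            min_len = 18L, max_len = 36L, genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  gr <- if (format == "bam") {
    read_bam_alignments(path)
  } else {
    read_bed_alignments(path)
  }
  if (!is.null(genome)) {
    known <- if (is.character(genome)) genome else names(genome)
    bad <- setdiff(unique(as.character(seqnames(gr))), known)
    if (length(bad) > 0L) {
      stop_ctx("unknown chromosome(s) %s; genome has: %s",
               paste(bad, collapse = ", "), paste(known, collapse = ", "))
    }
  }
  mcols(gr)$weight <- 1 / mcols(gr)$multiplicity
  mcols(gr)$library <- rep(library_label, length(gr))
  mcols(gr)$flagged <- width(gr) < min_len | width(gr) > max_len
  gr
}

read_bed_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(seq = character(0),
                                      multiplicity = integer(0),
                                      name = character(0))
    return(gr)
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    stop_ctx("malformed BED record at line %d: '%s'", bad[1L], lines[bad[1L]])
  }
  get_field <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  }, character(1))
  chrom <- get_field(1L)
  start0 <- suppressWarnings(as.integer(get_field(2L)))
  end0 <- suppressWarnings(as.integer(get_field(3L)))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0)
  if (length(bad) > 0L) {
    stop_ctx("malformed BED record at line %d: '%s'", bad[1L], lines[bad[1L]])
  }
  name <- get_field(4L)
  mult <- suppressWarnings(as.integer(get_field(5L)))
  mult[is.na(mult) | mult < 1L] <- 1L
  strands <- get_field(6L)
  strands[is.na(strands) | !strands %in% c("+", "-")] <- "*"
  seqs <- get_field(7L)
  looks_seq <- !is.na(seqs) & grepl("^[ACGTUNacgtun]+$", seqs)
  seqs[!looks_seq] <- NA_character_
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strands)
  mcols(gr) <- S4Vectors::DataFrame(seq = seqs, multiplicity = mult,
                                    name = name)
  gr
}

read_bam_alignments <- function(path) {
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth", "strand", "seq"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  n <- length(res$pos)
  if (n == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(seq = character(0),
                                      multiplicity = integer(0),
                                      name = character(0))
    return(gr)
  }
  mult <- res$tag$NH
  if (is.null(mult)) mult <- rep(1L, n)
  mult[is.na(mult) | mult < 1L] <- 1L
  gr <- GRanges(res$rname, IRanges(res$pos, width = res$qwidth),
                strand = res$strand)
  mcols(gr) <- S4Vectors::DataFrame(seq = as.character(res$seq),
                                    multiplicity = mult,
                                    name = NA_character_)
  gr
}

#' Compute a weighted coverage track
#'
#' Per-position read coverage per chromosome, either from uniquely
#' mapping reads only (`mode = "unique"`, each read weight 1) or from
#' all reads with each read's contribution divided by its number of
#' genomic matching locations (`mode = "reweighted"`).
#'
#' @param reads `GRanges` from [load_alignments()].
#' @param mode `"reweighted"` (default) or `"unique"`.
#' @param strand_mode `"both"` (default), `"+"` or `"-"`: restrict to
#'   reads on one strand or combine both.
#' @param seqlengths Optional named vector of chromosome lengths fixing
#'   the track widths (otherwise tracks end at the last covered base).
#' @param include_flagged Include reads flagged as outside the length
#'   bounds (default `FALSE`).
#' @return An [IRanges::RleList] of per-chromosome coverage, with
#'   `metadata()` recording `mode` and `strand_mode`.
#' @export
compute_coverage <- function(reads, mode = c("reweighted", "unique"),
                             strand_mode = c("both", "+", "-"),
                             seqlengths = NULL, include_flagged = FALSE) {
  mode <- match.arg(mode)
  strand_mode <- match.arg(strand_mode)
  if (!include_flagged && !is.null(mcols(reads)$flagged)) {
    reads <- reads[!mcols(reads)$flagged]
  }
  if (strand_mode != "both") {
    reads <- reads[as.character(strand(reads)) == strand_mode]
  }
  mult <- mcols(reads)$multiplicity
  if (is.null(mult)) mult <- rep(1L, length(reads))
  if (mode == "unique") {
    keep <- mult == 1L
    reads <- reads[keep]
    w <- rep(1, length(reads))
  } else {
    w <- 1 / mult
  }
  gr <- granges(reads)
  if (!is.null(seqlengths)) {
    gr <- GRanges(seqnames(reads), ranges(reads),
                  seqinfo = GenomeInfoDb::Seqinfo(names(seqlengths),
                                                  unname(seqlengths)))
  }
  cov <- coverage(gr, weight = w)
  metadata(cov) <- list(mode = mode, strand_mode = strand_mode)
  cov
}

#' Total mass of a coverage track set
#'
#' Sum of per-position values over all chromosomes; equals the sum of
#' `weight * length` over contributing reads.
#'
#' @param cov An `RleList` from [compute_coverage()].
#' @return A number.
#' @export
coverage_mass <- function(cov) {
  sum(vapply(cov, function(x) sum(as.numeric(runValue(x)) * runLength(x)),
             numeric(1)))
}
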