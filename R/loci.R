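#' Cluster reads into sRNA-producing loci
#'
#' Single-linkage clustering of aligned reads along each chromosome:
#' two reads belong to the same locus iff they are connected by a chain
#' of reads whose pairwise genomic gap (end-to-start distance between
#' the nearest read ends) is less than `max_gap`. Loci supported by
#' fewer than `min_reads` reads are discarded. Strand is ignored for
#' clustering; each locus records its strand composition.
#'
#' Each emitted locus spans `min(start)..max(end)` of its member reads
#' and carries summary statistics used by the distribution classifier:
#' `strand_fraction` (fraction of reads on the majority strand),
#' `dominant_length` (modal read length, ties broken toward the shorter
#' length), and `localization` (fraction of reads whose 5' ends fall
#' within +/- 2 nt of the modal 5' end).
#'
#' @param reads `GRanges` of aligned reads (see [load_alignments()]).
#' @param max_gap Reads closer than this many bp are linked (default
#'   100).
#' @param min_reads Minimum supporting reads per emitted locus
#'   (default 10).
#' @param include_flagged Include out-of-length-range reads (default
#'   `FALSE`).
#' @param classify Add the PILE/DISTRIBUTED call via
#'   [classify_distribution()] (default `TRUE`).
#' @param S,L Thresholds passed to [classify_distribution()].
#' @return `GRanges` of loci with metadata columns `read_count`,
#'   `weighted_count`, `strand_fraction`, `dominant_length`,
#'   `localization`, `libraries` and (if `classify`)
#'   `distribution_class`.
#' @export
cluster_srna_loci <- function(reads, max_gap = 100L, min_reads = 10L,
                              include_flagged = FALSE, classify = TRUE,
                              S = 0.9, L = 0.8) {
  if (!include_flagged && !is.null(mcols(reads)$flagged)) {
    reads <- reads[!mcols(reads)$flagged]
  }
  if (length(reads) == 0L) {
    loci <- GRanges()
    mcols(loci) <- S4Vectors::DataFrame(read_count = integer(0),
                                        weighted_count = numeric(0),
                                        strand_fraction = numeric(0),
                                        dominant_length = numeric(0),
                                        localization = numeric(0),
                                        libraries = character(0))
    return(loci)
  }
  # reduce() merges ranges separated by a gap < min.gapwidth, which is
  # exactly the "aligned less than max_gap bp from each other" rule
  loci <- reduce(granges(reads), min.gapwidth = max_gap,
                 ignore.strand = TRUE)
  hits <- findOverlaps(reads, loci, ignore.strand = TRUE)
  idx <- split(queryHits(hits), subjectHits(hits))
  stats <- locus_member_stats(reads, idx, length(loci))
  mcols(loci) <- stats
  keep <- stats$read_count >= min_reads
  loci <- loci[keep]
  if (classify) {
    mcols(loci)$distribution_class <- classify_distribution(loci, S = S,
                                                            L = L)
  }
  loci
}

locus_member_stats <- function(reads, idx, n_loci) {
  w <- mcols(reads)$weight
  if (is.null(w)) w <- rep(1, length(reads))
  lib <- mcols(reads)$library
  if (is.null(lib)) lib <- rep("lib1", length(reads))
  fp <- five_prime_pos(reads)
  str <- as.character(strand(reads))
  len <- width(reads)
  one <- function(i) {
    ii <- idx[[as.character(i)]]
    if (is.null(ii)) {
      return(list(0L, 0, NA_real_, NA_real_, NA_real_, ""))
    }
    s <- str[ii]
    plus <- sum(s == "+")
    minus <- sum(s == "-")
    sf <- max(plus, minus) / max(1L, plus + minus)
    # dominant length: modal, ties toward the shorter length
    dl <- modal_value(len[ii])
    # localization: 5' ends within +/-2 nt of the modal 5' end
    m5 <- modal_value(fp[ii])
    loc <- mean(abs(fp[ii] - m5) <= 2)
    list(length(ii), sum(w[ii]), sf, dl, loc,
         paste(sort(unique(lib[ii])), collapse = ","))
  }
  res <- lapply(seq_len(n_loci), one)
  S4Vectors::DataFrame(
    read_count = vapply(res, function(x) as.integer(x[[1]]), integer(1)),
    weighted_count = vapply(res, function(x) x[[2]], numeric(1)),
    strand_fraction = vapply(res, function(x) x[[3]], numeric(1)),
    dominant_length = vapply(res, function(x) x[[4]], numeric(1)),
    localization = vapply(res, function(x) x[[5]], numeric(1)),
    libraries = vapply(res, function(x) x[[6]], character(1))
  )
}

#' Classify the read distribution of a locus
#'
#' A locus is a `PILE` -- the archetype of a processed sRNA, thousands
#' of copies of the same sequence stacked on a single strand -- iff its
#' majority-strand fraction is at least `S` and its 5'-end localization
#' at least `L`; otherwise it is `DISTRIBUTED` (overlapping reads on
#' both strands, the TE/methylation-associated archetype).
#'
#' @param loci `GRanges` with `strand_fraction` and `localization`
#'   metadata columns (from [cluster_srna_loci()]).
#' @param S Strand-specificity threshold (default 0.9).
#' @param L Localization threshold (default 0.8).
#' @return Character vector, `"PILE"` or `"DISTRIBUTED"` per locus.
#' @export
classify_distribution <- function(loci, S = 0.9, L = 0.8) {
  sf <- mcols(loci)$strand_fraction
  loc <- mcols(loci)$localization
  ifelse(!is.na(sf) & !is.na(loc) & sf >= S & loc >= L,
         "PILE", "DISTRIBUTED")
}

#' Filter PILE loci to candidate processed-sRNA loci
#'
#' Applies the candidate filters to PILE-classified loci: dominant
#' fragment length within `[min_len, max_len]` (default 19-29 nt),
#' strand specificity and localization thresholds, a sequence-complexity
#' test on the dominant fragment (Shannon entropy and maximal
#' dinucleotide fraction), and a degradation proxy rejecting poorly
#' localized loci inside annotated structural RNAs. Retained loci are
#' typed by annotation overlap as tRNA-associated, known-ncRNA or
#' intergenic-novel.
#'
#' @param loci `GRanges` from [cluster_srna_loci()].
#' @param annotations An `AnnotationSet`; the genome sequence is
#'   required for the complexity test.
#' @param min_len,max_len Dominant-length bounds (19 and 29 nt).
#' @param S,L Strand-specificity / localization thresholds (0.9, 0.8).
#' @param entropy_min Minimum Shannon entropy in bits/nt (1.5).
#' @param dinuc_max Maximum single-dinucleotide fraction (0.6).
#' @param structural_types `ncrnas` annotation types treated as abundant
#'   structural RNAs for the degradation filter.
#' @return `GRanges` of all input loci with per-filter logical columns
#'   (`pass_length`, `pass_strand`, `pass_localization`,
#'   `pass_complexity`, `pass_degradation`, `pass_all`) and a
#'   `candidate_type` column; candidates are the subset with
#'   `pass_all == TRUE`.
#' @export
filter_candidates <- function(loci, annotations, min_len = 19L,
                              max_len = 29L, S = 0.9, L = 0.8,
                              entropy_min = 1.5, dinuc_max = 0.6,
                              structural_types = c("rRNA", "rRNA_gene",
                                                   "snoRNA")) {
  if (is.null(annotations$genome)) {
    stop_ctx("genome sequence unavailable: required for the low-complexity filter")
  }
  if (length(loci) == 0L) {
    mcols(loci)$pass_all <- logical(0)
    mcols(loci)$candidate_type <- character(0)
    return(loci)
  }
  dl <- mcols(loci)$dominant_length
  sf <- mcols(loci)$strand_fraction
  loc <- mcols(loci)$localization
  pass_length <- !is.na(dl) & dl >= min_len & dl <= max_len
  pass_strand <- !is.na(sf) & sf >= S
  pass_localization <- !is.na(loc) & loc >= L
  cons <- locus_consensus_seq(loci, annotations$genome)
  pass_complexity <- vapply(cons, function(s) {
    seq_entropy(s) >= entropy_min && max_dinuc_fraction(s) < dinuc_max
  }, logical(1))
  # degradation proxy: fully inside a structural RNA and lacking a
  # localized 5'-end mode
  structural <- annotations$ncrnas
  if (!is.null(structural) && !is.null(mcols(structural)$type)) {
    structural <- structural[as.character(mcols(structural)$type) %in%
                               structural_types]
  }
  inside <- if (is.null(structural) || length(structural) == 0L) {
    rep(FALSE, length(loci))
  } else {
    overlapsAny(loci, structural, type = "within", ignore.strand = TRUE)
  }
  pass_degradation <- !(inside & (is.na(loc) | loc < L))
  pass_all <- pass_length & pass_strand & pass_localization &
    pass_complexity & pass_degradation
  type <- rep("intergenic-novel", length(loci))
  if (!is.null(annotations$trnas)) {
    type[overlapsAny(loci, annotations$trnas, ignore.strand = TRUE)] <-
      "tRNA-associated"
  }
  if (!is.null(annotations$ncrnas)) {
    is_nc <- overlapsAny(loci, annotations$ncrnas, ignore.strand = TRUE)
    type[is_nc & type == "intergenic-novel"] <- "known-ncRNA"
  }
  mcols(loci)$pass_length <- pass_length
  mcols(loci)$pass_strand <- pass_strand
  mcols(loci)$pass_localization <- pass_localization
  mcols(loci)$pass_complexity <- pass_complexity
  mcols(loci)$pass_degradation <- pass_degradation
  mcols(loci)$pass_all <- pass_all
  mcols(loci)$candidate_type <- type
  loci
}

# Genomic sequence of the dominant fragment of each locus (modal 5' end
# on the majority strand, dominant length), used for the complexity test.
locus_consensus_seq <- function(loci, genome) {
  vapply(seq_along(loci), function(i) {
    chrom <- as.character(seqnames(loci))[i]
    if (!chrom %in% names(genome)) {
      stop_ctx("locus chromosome '%s' not in genome (%s)", chrom,
               paste(names(genome), collapse = ", "))
    }
    s <- max(1L, start(loci)[i])
    e <- min(end(loci)[i], length(genome[[chrom]]))
    as.character(subseq(genome[[chrom]], s, e))
  }, character(1))
}

#' Merge candidate loci across libraries
#'
#' Takes the union of candidate genomic intervals across libraries.
#' Each merged locus records which libraries support it and in how many
#' libraries it was detected.
#'
#' @param candidate_sets Named list of `GRanges`, one per library.
#' @return `GRanges` of merged intervals with `libraries` (comma
#'   separated) and `support` (number of detecting libraries) columns.
#' @export
merge_across_libraries <- function(candidate_sets) {
  stopifnot(length(candidate_sets) >= 1L)
  if (is.null(names(candidate_sets))) {
    names(candidate_sets) <- paste0("lib", seq_along(candidate_sets))
  }
  all_gr <- unlist(GRangesList(lapply(candidate_sets, granges)),
                   use.names = FALSE)
  if (length(all_gr) == 0L) {
    merged <- GRanges()
    mcols(merged) <- S4Vectors::DataFrame(libraries = character(0),
                                          support = integer(0))
    return(merged)
  }
  merged <- reduce(all_gr, ignore.strand = TRUE)
  libs <- lapply(seq_along(merged), function(i) {
    hit <- vapply(candidate_sets, function(gr) {
      length(gr) > 0L &&
        any(overlapsAny(merged[i], gr, ignore.strand = TRUE))
    }, logical(1))
    names(candidate_sets)[hit]
  })
  mcols(merged)$libraries <- vapply(libs, paste, character(1),
                                    collapse = ",")
  mcols(merged)$support <- lengths(libs)
  merged
}
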