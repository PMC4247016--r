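#' Build a candidate precursor sequence
#'
#' Extends a candidate locus by `flank` nt on both sides (clipped at
#' chromosome ends with a warning) and extracts the genomic sequence,
#' reverse-complemented for minus-strand candidates.
#'
#' @param candidate A length-1 `GRanges`.
#' @param genome `DNAStringSet`.
#' @param flank Extension in nt on each side (default 50).
#' @return List: `interval` (`GRanges` of the extended region) and
#'   `sequence` (character, DNA alphabet, candidate-strand orientation).
#' @export
build_precursor <- function(candidate, genome, flank = 50L) {
  stopifnot(length(candidate) == 1L)
  chrom <- as.character(seqnames(candidate))
  if (!chrom %in% names(genome)) {
    stop_ctx("chromosome '%s' not in genome (%s)", chrom,
             paste(names(genome), collapse = ", "))
  }
  clen <- length(genome[[chrom]])
  s <- start(candidate) - flank
  e <- end(candidate) + flank
  if (s < 1L || e > clen) {
    warn_ctx("precursor clipped at chromosome boundary (%d..%d on %s of length %d)",
             s, e, chrom, clen)
    s <- max(1L, s)
    e <- min(clen, e)
  }
  seq <- subseq(genome[[chrom]], s, e)
  if (as.character(strand(candidate)) == "-") {
    seq <- reverseComplement(seq)
  }
  interval <- GRanges(chrom, IRanges(s, e),
                      strand = strand(candidate))
  list(interval = interval, sequence = as.character(seq))
}

#' Propose mature fragments from candidate reads
#'
#' Groups reads into distinct fragments by (start, end, strand), ranks
#' them by read count, and returns the top `max_n` (default 6) as
#' putative mature sRNAs. Ties are broken by leftmost start, then
#' shortest length.
#'
#' @param reads `GRanges` of reads over the candidate region.
#' @param max_n Maximum fragments returned (default 6).
#' @return `GRanges` of distinct fragments with a `count` column,
#'   most abundant first.
#' @export
propose_matures <- function(reads, max_n = 6L) {
  stopifnot(length(reads) >= 1L)
  key <- paste(as.character(seqnames(reads)), start(reads), end(reads),
               as.character(strand(reads)), sep = ":")
  tab <- table(key)
  first <- reads[!duplicated(key)]
  counts <- as.integer(tab[paste(as.character(seqnames(first)),
                                 start(first), end(first),
                                 as.character(strand(first)),
                                 sep = ":")])
  ord <- order(-counts, start(first), width(first))
  out <- first[ord]
  mcols(out) <- S4Vectors::DataFrame(count = counts[ord])
  head(out, max_n)
}

#' Empirical p-value for a precursor's minimum free energy
#'
#' Draws `n` random genomic regions of the same length (uniform over
#' positions, strand chosen with probability 1/2), folds them with the
#' same backend, and reports the proportion of random regions with an
#' MFE lower than the candidate's `m`:
#' `p = #\{MFE_random < m\} / n`. A stable candidate (very negative
#' `m`) therefore has few random regions below it and a small `p`; the
#' structure is deemed significant when `p < alpha` (default 5%).
#'
#' @param mfe Candidate MFE `m`.
#' @param length Region length in nt.
#' @param genome `DNAStringSet`.
#' @param n Number of random regions (default 1000).
#' @param seed Optional RNG seed, recorded in the output.
#' @param backend,temperature Passed to [fold_rna()]; use the backend
#'   that produced `mfe`.
#' @param alpha Significance level (default 0.05).
#' @return List: `p`, `significant`, `n`, `seed`, `backend`,
#'   `sampled_mfe` (the null MFE sample).
#' @export
empirical_mfe_pvalue <- function(mfe, length, genome, n = 1000L,
                                 seed = NULL,
                                 backend = c("auto", "rnafold",
                                             "basepair"),
                                 temperature = 24, alpha = 0.05) {
  backend <- match.arg(backend)
  if (!is.null(seed)) set.seed(seed)
  lens <- width(genome)
  if (all(lens < length)) {
    stop_ctx("region length %d exceeds the longest chromosome (%d)",
             length, max(lens))
  }
  ok <- which(lens >= length)
  npos <- lens[ok] - length + 1L
  chrom_idx <- ok[sample.int(length(ok), n, replace = TRUE,
                             prob = npos / sum(npos))]
  starts <- vapply(chrom_idx, function(i) {
    sample.int(lens[i] - length + 1L, 1L)
  }, integer(1))
  minus <- runif(n) < 0.5
  seqs <- vapply(seq_len(n), function(j) {
    s <- subseq(genome[[chrom_idx[j]]], starts[j],
                starts[j] + length - 1L)
    if (minus[j]) s <- reverseComplement(s)
    as.character(s)
  }, character(1))
  folds <- fold_rna(seqs, backend = backend, temperature = temperature)
  p <- mean(folds$mfe < mfe)
  list(p = p, significant = p < alpha, n = n, seed = seed,
       backend = folds$backend[1L], sampled_mfe = folds$mfe)
}

#' Assess the mature/star duplex geometry of a hairpin
#'
#' Locates the putative mature sRNA on the folded precursor, infers the
#' star as the base-pairing partner span shifted by 2 nt toward its 3'
#' end (standard duplex geometry), and checks whether each 3' end of
#' the mature/star duplex extends its partner's paired region by
#' exactly 2 nt -- the signature of processing by Dicer, which leaves
#' 2 nt 3' overhangs at both ends.
#'
#' @param structure Dot-bracket string of the precursor.
#' @param mature Integer vector `c(start, end)` of the mature within
#'   the precursor (1-based, inclusive).
#' @param star Optional `c(start, end)` of an observed star; inferred
#'   from the pairing when omitted.
#' @param min_paired_frac Minimum fraction of mature positions that
#'   must be paired for the mature to count as stem-located
#'   (default 0.5).
#' @return List: `status` (`both_3p_2nt`, `one_side_only`, `none`),
#'   `star` (`c(start, end)` or `NULL`), `overhang_mature`,
#'   `overhang_star` (nt, `NA` when not assessable).
#' @export
assess_duplex <- function(structure, mature, star = NULL,
                          min_paired_frac = 0.5) {
  pt <- pair_table(structure)
  n <- length(pt)
  ms <- mature[1]
  me <- mature[2]
  stopifnot(ms >= 1L, me <= n, ms <= me)
  mpos <- ms:me
  paired <- mpos[pt[mpos] > 0L]
  if (length(paired) / length(mpos) < min_paired_frac) {
    return(list(status = "none", star = NULL,
                overhang_mature = NA_integer_,
                overhang_star = NA_integer_))
  }
  if (is.null(star)) {
    partners <- pt[paired]
    star <- c(min(partners) + 2L, max(partners) + 2L)
    star[2] <- min(star[2], n)
    star[1] <- max(1L, star[1])
  }
  ss <- star[1]
  se <- star[2]
  spos <- ss:se
  # mature 3' overhang: mature tail beyond the last mature base paired
  # into the star
  m_in_s <- mpos[pt[mpos] >= ss & pt[mpos] <= se]
  s_in_m <- spos[pt[spos] >= ms & pt[spos] <= me]
  if (length(m_in_s) == 0L || length(s_in_m) == 0L) {
    return(list(status = "none", star = star,
                overhang_mature = NA_integer_,
                overhang_star = NA_integer_))
  }
  overhang_mature <- me - max(m_in_s)
  overhang_star <- se - max(s_in_m)
  two_m <- overhang_mature == 2L
  two_s <- overhang_star == 2L
  status <- if (two_m && two_s) {
    "both_3p_2nt"
  } else if (two_m || two_s) {
    "one_side_only"
  } else {
    "none"
  }
  list(status = status, star = star,
       overhang_mature = overhang_mature,
       overhang_star = overhang_star)
}

#' Evaluate a candidate locus as a miRNA-like hairpin
#'
#' Full hairpin evaluation of one candidate locus: extends the
#' candidate into a precursor ([build_precursor()]), folds it
#' ([fold_rna()]), computes the empirical MFE p-value against random
#' genomic regions ([empirical_mfe_pvalue()]), proposes mature
#' fragments from the read data ([propose_matures()]), and assesses
#' the mature/star duplex geometry ([assess_duplex()]).
#'
#' Verdicts: `canonical_miRNA` (significant hairpin, mature on a stem,
#' 2 nt 3' overhangs on both duplex ends), `miRNA_like` (significant
#' hairpin with mature and star but overhangs on at most one side),
#' `rejected` otherwise. With a fixed `seed` the evaluation is
#' reproducible.
#'
#' @param candidate Length-1 `GRanges` candidate locus.
#' @param reads `GRanges` of reads (those overlapping the candidate are
#'   used for mature proposal).
#' @param genome `DNAStringSet`.
#' @param flank Precursor extension (default 50 nt).
#' @param n_perm Random regions for the empirical p-value
#'   (default 1000).
#' @param seed RNG seed recorded in the result.
#' @param backend,temperature Folding backend settings (see
#'   [fold_rna()]).
#' @param alpha Significance level for the empirical p-value (0.05).
#' @return List with `precursor`, `structure`, `mfe`, `empirical_p`,
#'   `significant`, `matures` (`GRanges`), `mature_local`
#'   (precursor-relative coordinates of the top mature), `duplex`
#'   (from [assess_duplex()]), `verdict`, `seed`, `backend`.
#' @export
evaluate_hairpin <- function(candidate, reads, genome, flank = 50L,
                             n_perm = 1000L, seed = NULL,
                             backend = c("auto", "rnafold", "basepair"),
                             temperature = 24, alpha = 0.05) {
  backend <- match.arg(backend)
  prec <- build_precursor(candidate, genome, flank = flank)
  fold <- fold_rna(prec$sequence, backend = backend,
                   temperature = temperature)
  emp <- empirical_mfe_pvalue(fold$mfe, nchar(prec$sequence), genome,
                              n = n_perm, seed = seed,
                              backend = backend,
                              temperature = temperature, alpha = alpha)
  over <- reads[overlapsAny(reads, candidate, ignore.strand = TRUE)]
  matures <- if (length(over) > 0L) propose_matures(over) else GRanges()
  duplex <- list(status = "none", star = NULL,
                 overhang_mature = NA_integer_,
                 overhang_star = NA_integer_)
  mature_local <- NULL
  if (length(matures) > 0L) {
    m <- matures[1L]
    ps <- start(prec$interval)
    pe <- end(prec$interval)
    if (start(m) >= ps && end(m) <= pe) {
      if (as.character(strand(candidate)) == "-") {
        mature_local <- c(pe - end(m) + 1L, pe - start(m) + 1L)
      } else {
        mature_local <- c(start(m) - ps + 1L, end(m) - ps + 1L)
      }
      duplex <- assess_duplex(fold$structure, mature_local)
    }
  }
  verdict <- if (!emp$significant || is.null(mature_local) ||
                 duplex$status == "none") {
    "rejected"
  } else if (duplex$status == "both_3p_2nt") {
    "canonical_miRNA"
  } else {
    "miRNA_like"
  }
  list(precursor = prec, structure = fold$structure, mfe = fold$mfe,
       empirical_p = emp$p, significant = emp$significant,
       matures = matures, mature_local = mature_local, duplex = duplex,
       verdict = verdict, seed = seed, backend = fold$backend[1L],
       temperature = temperature)
}
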