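#' Classify tRNA-derived fragments (tRFs)
#'
#' Places each fragment on its tRNA gene model and assigns one of the
#' tRF classes observed in small-RNA sequencing data:
#'
#' * `3p_short` -- short fragment (default 17-22 nt) whose 3' end lies
#'   within `slack` nt of the mature 3' terminus; these typically carry
#'   the post-transcriptionally added CCA.
#' * `3p_long` -- long fragment (default 30-36 nt) anchored at the 3'
#'   end; typically lacks CCA.
#' * `5p_long` -- long fragment anchored at the 5' end.
#' * `half_tRNA` -- fragment spanning the 5' end through the anticodon
#'   loop.
#' * `dloop_anticodon` -- short fragment overlapping the D loop or the
#'   anticodon loop without 3' anchoring.
#' * `unclassified` otherwise.
#'
#' Classes are mutually exclusive; when several rules match, the most
#' specific wins: `half_tRNA` > `3p_short`/`3p_long` > `5p_long` >
#' `dloop_anticodon`.
#'
#' @param fragments `GRanges` of reads overlapping tRNA genes, with an
#'   optional `seq` metadata column (needed for CCA detection).
#' @param trnas tRNA gene model `GRanges` (see [read_trna_table()]).
#' @param short_range,long_range Closed length intervals
#'   operationalizing "around 19 nt" and "30-35 nt" (defaults
#'   `c(17, 22)` and `c(30, 36)`).
#' @param slack Anchor tolerance in nt at either terminus (default 3).
#' @return Data frame with one row per fragment: `trna_id`, `isotype`,
#'   `anticodon`, `length`, `off5` / `off3` (distance of the fragment
#'   ends from the mature 5' / 3' termini, nt), `trf_class` and `cca`
#'   (`present` / `absent` / `not_applicable`; `NA` when the fragment
#'   sequence is unavailable).
#' @export
classify_trf <- function(fragments, trnas, short_range = c(17L, 22L),
                         long_range = c(30L, 36L), slack = 3L) {
  validate_trna_model(trnas)
  hits <- findOverlaps(fragments, trnas, ignore.strand = TRUE)
  if (length(fragments) > 0L &&
      length(unique(queryHits(hits))) < length(fragments)) {
    bad <- setdiff(seq_along(fragments), unique(queryHits(hits)))
    stop_ctx("fragment %d does not overlap any tRNA gene", bad[1L])
  }
  # a fragment overlapping several tRNAs is assigned to the first
  first <- !duplicated(queryHits(hits))
  qi <- queryHits(hits)[first]
  ti <- subjectHits(hits)[first]
  f <- fragments[qi]
  t <- trnas[ti]
  tm <- mcols(t)
  minus <- as.character(strand(t)) == "-"
  # fragment end offsets relative to the mature tRNA, strand-aware:
  # off5 = distance of fragment 5' end from the tRNA 5' terminus,
  # off3 = distance of fragment 3' end from the mature 3' terminus
  # (negative when the fragment extends beyond, e.g. appended CCA)
  off5 <- ifelse(minus, end(t) - end(f), start(f) - start(t))
  off3 <- ifelse(minus, start(f) - start(t), end(t) - end(f))
  len <- width(f)
  # loop intervals in tRNA-relative coordinates (0-based offsets)
  rel <- function(gs, ge) {
    s <- ifelse(minus, end(t) - ge, gs - start(t))
    e <- ifelse(minus, end(t) - gs, ge - start(t))
    cbind(s, e)
  }
  dloop <- rel(tm$dloop_start, tm$dloop_end)
  acloop <- rel(tm$anticodon_start, tm$anticodon_end)
  frag_rel_s <- off5
  frag_rel_e <- off5 + len - 1L
  overlaps_arm <- function(arm) {
    frag_rel_s <= arm[, 2] & frag_rel_e >= arm[, 1]
  }
  anchored5 <- abs(off5) <= slack
  anchored3 <- abs(off3) <= slack
  is_short <- len >= short_range[1] & len <= short_range[2]
  is_long <- len >= long_range[1] & len <= long_range[2]
  # half tRNA: from the 5' end to a cleavage inside the anticodon loop
  # (no slack -- a long 5' tRF ends before the loop, a half ends in it)
  ends_in_acloop <- frag_rel_e >= acloop[, 1] & frag_rel_e <= acloop[, 2]
  cls <- rep("unclassified", length(f))
  cls[is_short & overlaps_arm(dloop) & !anchored3] <- "dloop_anticodon"
  cls[is_short & overlaps_arm(acloop) & !anchored3] <- "dloop_anticodon"
  cls[is_long & anchored5] <- "5p_long"
  cls[is_long & anchored3] <- "3p_long"
  cls[is_short & anchored3] <- "3p_short"
  cls[anchored5 & ends_in_acloop & len > short_range[2]] <- "half_tRNA"
  seqs <- mcols(f)$seq
  if (is.null(seqs)) seqs <- rep(NA_character_, length(f))
  out <- data.frame(
    fragment = qi,
    trna_id = tm$trna_id,
    isotype = if (!is.null(tm$isotype)) tm$isotype else NA_character_,
    anticodon = if (!is.null(tm$anticodon)) tm$anticodon else
      NA_character_,
    length = len,
    off5 = off5,
    off3 = off3,
    trf_class = cls,
    stringsAsFactors = FALSE
  )
  out$cca <- detect_cca(seqs, cls)
  out[order(out$fragment), , drop = FALSE]
}

#' Detect the 3'-terminal CCA on tRNA fragments
#'
#' The trinucleotide CCA is added to the 3' end of trimmed tRNA
#' intermediates; its presence distinguishes sub-populations of
#' 3'-anchored tRFs. Detection uses the read sequence (not the genome),
#' so both genome-templated and post-transcriptionally added CCA are
#' recognized. Non-3'-anchored classes get `not_applicable`.
#'
#' @param seqs Character vector of fragment sequences (DNA or RNA
#'   alphabet), `NA` allowed.
#' @param classes tRF class per fragment (see [classify_trf()]).
#' @return Character vector: `present`, `absent`, `not_applicable`, or
#'   `NA` where the sequence is missing for a 3'-anchored class.
#' @export
detect_cca <- function(seqs, classes) {
  applicable <- classes %in% c("3p_short", "3p_long")
  out <- rep("not_applicable", length(classes))
  s <- as_dna(ifelse(is.na(seqs), "", seqs))
  last3 <- substring(s, pmax(1L, nchar(s) - 2L), nchar(s))
  out[applicable] <- ifelse(is.na(seqs[applicable]), NA_character_,
                            ifelse(last3[applicable] == "CCA",
                                   "present", "absent"))
  out
}
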