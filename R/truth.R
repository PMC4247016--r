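#' Compare pipeline outputs with generator truth
#'
#' Recovery report against the planted features of a synthetic bundle:
#' precision and recall of locus detection (any-overlap matching),
#' agreement of distribution-class labels on matched loci, agreement of
#' tRF class and CCA labels per read, and the period recovery error of
#' periodic-region calls.
#'
#' @param loci Detected loci `GRanges` (from [cluster_srna_loci()]),
#'   optional.
#' @param truth_loci Truth table of planted loci (bundle
#'   `truth$loci`), optional.
#' @param trf Classified tRF data frame (from [classify_trf()]) with a
#'   `read_id` column, optional.
#' @param truth_trf Truth table of planted tRF reads (bundle
#'   `truth$trf`), optional.
#' @param periodic Called periodic regions (from
#'   [call_periodic_regions()]), optional.
#' @param truth_periodic Truth table of planted periodic regions
#'   (bundle `truth$periodic`), optional.
#' @param class_filter Restrict locus precision/recall to one planted
#'   class (e.g. `"PILE"`); `NULL` for all.
#' @return List of recovery statistics; components are `NULL` when the
#'   corresponding inputs were not supplied.
#' @export
truth_compare <- function(loci = NULL, truth_loci = NULL, trf = NULL,
                          truth_trf = NULL, periodic = NULL,
                          truth_periodic = NULL, class_filter = NULL) {
  out <- list()
  if (!is.null(loci) && !is.null(truth_loci)) {
    tl <- truth_loci
    det <- loci
    if (!is.null(class_filter)) {
      tl <- tl[tl$class == class_filter, , drop = FALSE]
      det <- det[mcols(det)$distribution_class == class_filter]
    }
    tgr <- GRanges(tl$chrom, IRanges(tl$start, tl$end))
    recall <- if (length(tgr) > 0L) {
      mean(overlapsAny(tgr, det, ignore.strand = TRUE))
    } else NA_real_
    precision <- if (length(det) > 0L) {
      mean(overlapsAny(det, tgr, ignore.strand = TRUE))
    } else NA_real_
    # class agreement over all matched locus pairs (unfiltered)
    tgr_all <- GRanges(truth_loci$chrom,
                       IRanges(truth_loci$start, truth_loci$end))
    hits <- findOverlaps(loci, tgr_all, ignore.strand = TRUE)
    agree <- if (length(hits) > 0L) {
      mean(mcols(loci)$distribution_class[queryHits(hits)] ==
             truth_loci$class[subjectHits(hits)])
    } else NA_real_
    out$loci <- list(precision = precision, recall = recall,
                     n_detected = length(det), n_planted = length(tgr),
                     class_agreement = agree)
  }
  if (!is.null(trf) && !is.null(truth_trf)) {
    m <- merge(trf, truth_trf, by = "read_id",
               suffixes = c("_det", "_truth"))
    out$trf <- list(
      n = nrow(m),
      class_agreement = mean(m$trf_class_det == m$trf_class_truth),
      cca_agreement = mean(m$cca_det == m$cca_truth))
  }
  if (!is.null(periodic) && !is.null(truth_periodic)) {
    tgr <- GRanges(truth_periodic$chrom,
                   IRanges(truth_periodic$start, truth_periodic$end))
    dgr <- if (nrow(periodic) > 0L) {
      GRanges(periodic$chrom, IRanges(periodic$start, periodic$end))
    } else GRanges()
    hits <- findOverlaps(tgr, dgr, ignore.strand = TRUE)
    err <- rep(NA_real_, length(tgr))
    for (i in unique(queryHits(hits))) {
      det_p <- periodic$mean_period[subjectHits(hits)[queryHits(hits) ==
                                                        i]]
      err[i] <- min(abs(det_p - truth_periodic$period[i]))
    }
    out$periodic <- list(
      recall = if (length(tgr) > 0L) mean(!is.na(err)) else NA_real_,
      period_error = err)
  }
  out
}
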