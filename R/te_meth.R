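#' Reads per kilobase per million aligned reads
#'
#' Closed-form RPKM: `count * 1e9 / (length_nt * total_aligned)`. A
#' depth- and length-normalized summary of sRNA coverage on a region.
#'
#' @param count Reads (or weighted reads) in the region.
#' @param length_nt Region length in nt (> 0).
#' @param total_aligned Total aligned reads of the library (> 0).
#' @return Numeric RPKM.
#' @export
rpkm <- function(count, length_nt, total_aligned) {
  if (any(length_nt <= 0)) stop_ctx("zero-length region in RPKM")
  if (any(total_aligned <= 0)) stop_ctx("total_aligned must be > 0")
  count * 1e9 / (length_nt * total_aligned)
}

#' Per-region sRNA RPKM
#'
#' Counts reads overlapping each region (multimapper-reweighted by
#' default) and converts to RPKM.
#'
#' @param regions `GRanges` of regions (e.g. TEs).
#' @param reads `GRanges` of aligned reads.
#' @param total_aligned Total aligned reads; defaults to the (weighted)
#'   read total of `reads`.
#' @param weighted Use multimapper-reweighted counts (default `TRUE`);
#'   otherwise unique reads only.
#' @param include_flagged Include out-of-length-range reads (default
#'   `FALSE`).
#' @return Numeric vector of RPKM, one per region.
#' @export
srna_rpkm <- function(regions, reads, total_aligned = NULL,
                      weighted = TRUE, include_flagged = FALSE) {
  if (!include_flagged && !is.null(mcols(reads)$flagged)) {
    reads <- reads[!mcols(reads)$flagged]
  }
  mult <- mcols(reads)$multiplicity
  if (is.null(mult)) mult <- rep(1L, length(reads))
  if (weighted) {
    w <- 1 / mult
  } else {
    reads <- reads[mult == 1L]
    w <- rep(1, length(reads))
  }
  if (is.null(total_aligned)) total_aligned <- sum(w)
  hits <- findOverlaps(reads, regions, ignore.strand = TRUE)
  counts <- vapply(seq_along(regions), function(i) {
    sum(w[queryHits(hits)[subjectHits(hits) == i]])
  }, numeric(1))
  rpkm(counts, width(regions), total_aligned)
}

#' Methylation level of regions
#'
#' Fraction of methylation probes overlapping each region that are
#' called methylated. Regions with no overlapping probe return `NA`
#' (undefined) rather than zero.
#'
#' @param regions `GRanges`.
#' @param probes `GRanges` of probes with a binary `call` metadata
#'   column (see [load_annotations()]).
#' @return Data frame with columns `n_probes`, `n_methylated`, `level`.
#' @export
methylation_level <- function(regions, probes) {
  call <- mcols(probes)$call
  if (is.null(call)) call <- mcols(probes)$score
  if (is.null(call)) stop_ctx("probes need a 'call' (0/1) column")
  hits <- findOverlaps(probes, regions, ignore.strand = TRUE)
  n <- nm <- integer(length(regions))
  tab_n <- table(factor(subjectHits(hits), levels = seq_along(regions)))
  n <- as.integer(tab_n)
  meth_hits <- hits[call[queryHits(hits)] > 0]
  tab_m <- table(factor(subjectHits(meth_hits),
                        levels = seq_along(regions)))
  nm <- as.integer(tab_m)
  data.frame(n_probes = n, n_methylated = nm,
             level = ifelse(n > 0, nm / n, NA_real_))
}

#' Bin RPKM values into coverage classes
#'
#' `low` below 5, `middle` from 5 to 10 (boundaries inclusive, keeping
#' the bins exhaustive), `high` above 10.
#'
#' @param x Numeric RPKM values.
#' @param low,high Bin boundaries (defaults 5 and 10).
#' @return Factor with levels `low`, `middle`, `high`.
#' @export
bin_rpkm <- function(x, low = 5, high = 10) {
  out <- ifelse(x < low, "low", ifelse(x <= high, "middle", "high"))
  factor(out, levels = c("low", "middle", "high"))
}

#' Classify expression values into low/expressed
#'
#' Genes or TEs at or below the given percentile of all expression
#' values (default the 15th) are labelled lowly expressed.
#'
#' @param expressions Numeric expression values (RPKM, EST counts, ...).
#' @param percentile Percentile defining the low class (default 0.15).
#' @return Factor with levels `low`, `expressed`.
#' @export
expression_class <- function(expressions, percentile = 0.15) {
  stopifnot(length(expressions) >= 1L)
  thr <- quantile(expressions, percentile, na.rm = TRUE, names = FALSE)
  factor(ifelse(expressions <= thr, "low", "expressed"),
         levels = c("low", "expressed"))
}

#' Coverage/expression/methylation association tests
#'
#' The statistical battery relating sRNA coverage to expression and
#' DNA methylation:
#'
#' * one-sided Mann-Whitney U test of sRNA coverage (RPKM) in lowly/not
#'   expressed versus expressed regions (alternative: coverage greater
#'   in the low-expression group);
#' * Spearman rank and Pearson correlations between methylation level
#'   and sRNA RPKM;
#' * pairwise Spearman correlation matrix between library coverage
#'   vectors (when `library_matrix` is given).
#'
#' `wilcox.test()` computes an exact p-value for small tie-free samples
#' and a normal approximation with tie correction otherwise.
#'
#' @param rpkm Numeric per-region sRNA RPKM.
#' @param expr_class Factor from [expression_class()] (optional).
#' @param methylation Numeric per-region methylation level (optional).
#' @param library_matrix Optional numeric matrix (regions x libraries)
#'   of per-library coverage.
#' @param min_group Minimum group size for the rank test (default 3);
#'   smaller groups report `NA` with a warning.
#' @return List with elements `mann_whitney` (statistic, p.value, group
#'   sizes), `spearman`, `pearson`, and `library_correlation`.
#' @export
association_tests <- function(rpkm, expr_class = NULL,
                              methylation = NULL, library_matrix = NULL,
                              min_group = 3L) {
  out <- list()
  if (!is.null(expr_class)) {
    g_low <- rpkm[expr_class == "low"]
    g_exp <- rpkm[expr_class == "expressed"]
    if (length(g_low) < min_group || length(g_exp) < min_group) {
      warn_ctx("expression group too small for the rank test (%d vs %d)",
               length(g_low), length(g_exp))
      out$mann_whitney <- list(statistic = NA_real_, p.value = NA_real_,
                               n_low = length(g_low),
                               n_expressed = length(g_exp))
    } else {
      wt <- suppressWarnings(
        wilcox.test(g_low, g_exp, alternative = "greater"))
      out$mann_whitney <- list(statistic = unname(wt$statistic),
                               p.value = wt$p.value,
                               n_low = length(g_low),
                               n_expressed = length(g_exp))
    }
  }
  if (!is.null(methylation)) {
    ok <- complete.cases(methylation, rpkm)
    if (sum(ok) >= 3L && stats::sd(methylation[ok]) > 0 &&
        stats::sd(rpkm[ok]) > 0) {
      out$spearman <- cor(methylation[ok], rpkm[ok], method = "spearman")
      out$pearson <- cor(methylation[ok], rpkm[ok], method = "pearson")
    } else {
      out$spearman <- NA_real_
      out$pearson <- NA_real_
    }
  }
  if (!is.null(library_matrix)) {
    out$library_correlation <- cor(library_matrix, method = "spearman")
  }
  out
}

#' 5' nucleotide composition of reads
#'
#' Base frequencies at read positions 1 to `n_pos` (read orientation;
#' T is reported as U). TE-derived sRNA populations typically show a
#' strong 5'-U bias.
#'
#' @param seqs Character vector of read sequences, or a `GRanges` with
#'   a `seq` metadata column.
#' @param n_pos Number of 5' positions (default 5).
#' @return Matrix (4 x n_pos) of frequencies, rows A/C/G/U; each column
#'   sums to 1.
#' @export
five_prime_composition <- function(seqs, n_pos = 5L) {
  if (methods::is(seqs, "GRanges")) seqs <- mcols(seqs)$seq
  seqs <- as_rna(seqs[!is.na(seqs)])
  if (length(seqs) == 0L) stop_ctx("no read sequences available")
  bases <- c("A", "C", "G", "U")
  mat <- vapply(seq_len(n_pos), function(p) {
    b <- substring(seqs, p, p)
    b <- b[b %in% bases]
    tab <- table(factor(b, levels = bases))
    as.numeric(tab) / sum(tab)
  }, numeric(4))
  rownames(mat) <- bases
  colnames(mat) <- paste0("pos", seq_len(n_pos))
  mat
}

#' Per-region TE statistics table
#'
#' Convenience wrapper assembling the per-region statistics used by the
#' association analyses: region length, sRNA RPKM (and bin), methylation
#' level, expression and expression class. TE regions shorter than
#' `min_len` are dropped (annotation noise); family-level analyses
#' conventionally restrict further (e.g. > 300 bp).
#'
#' @param regions `GRanges` of TE regions with optional `family`
#'   metadata column.
#' @param reads `GRanges` of aligned reads.
#' @param probes Methylation probe `GRanges` (optional).
#' @param expression Numeric expression per region (optional). For
#'   autonomous TEs overlapping several gene models, supply the highest
#'   value.
#' @param total_aligned Total aligned reads (see [srna_rpkm()]).
#' @param min_len Minimum region length (default 50 nt).
#' @param percentile Low-expression percentile (default 0.15).
#' @return Data frame with one row per retained region.
#' @export
te_region_stats <- function(regions, reads, probes = NULL,
                            expression = NULL, total_aligned = NULL,
                            min_len = 50L, percentile = 0.15) {
  keep <- width(regions) > min_len
  regions <- regions[keep]
  if (!is.null(expression)) expression <- expression[keep]
  fam <- mcols(regions)$family
  if (is.null(fam)) fam <- rep(NA_character_, length(regions))
  df <- data.frame(
    chrom = as.character(seqnames(regions)),
    start = start(regions), end = end(regions),
    family = fam, length = width(regions),
    stringsAsFactors = FALSE)
  df$srna_rpkm <- srna_rpkm(regions, reads, total_aligned)
  df$rpkm_bin <- bin_rpkm(df$srna_rpkm)
  if (!is.null(probes)) {
    ml <- methylation_level(regions, probes)
    df$n_probes <- ml$n_probes
    df$methylation_level <- ml$level
  }
  if (!is.null(expression)) {
    df$expression <- expression
    df$expression_class <- expression_class(expression, percentile)
  }
  df
}
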