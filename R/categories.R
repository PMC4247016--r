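#' Assign each read to one genomic category
#'
#' Assigns every read to exactly one category under a configurable
#' priority order using an any-overlap (>= 1 bp) rule, ignoring strand.
#' Reads overlapping no annotation are `intergenic`.
#'
#' @param reads `GRanges` of aligned reads.
#' @param annotations An `AnnotationSet`.
#' @param priority Category priority, highest first. Categories map to
#'   annotation components: `tRNA` -> `trnas`, `ncRNA` -> `ncrnas`,
#'   `repeat` -> `repeats`, `gene` -> `genes`.
#' @return Factor of length `length(reads)` with levels
#'   `c(priority, "intergenic")`.
#' @export
assign_category <- function(reads, annotations,
                            priority = c("tRNA", "ncRNA", "repeat",
                                         "gene")) {
  comp <- c(tRNA = "trnas", ncRNA = "ncrnas", "repeat" = "repeats",
            gene = "genes")
  unknown <- setdiff(priority, names(comp))
  if (length(unknown) > 0L) {
    stop_ctx("unknown category in priority: %s",
             paste(unknown, collapse = ", "))
  }
  out <- rep("intergenic", length(reads))
  for (cat in rev(priority)) {
    ann <- annotations[[comp[[cat]]]]
    if (is.null(ann) || length(ann) == 0L) next
    out[overlapsAny(reads, ann, ignore.strand = TRUE)] <- cat
  }
  factor(out, levels = c(priority, "intergenic"))
}

#' Read-length histogram
#'
#' Counts of reads per length (default 18-36 nt) overall or split by a
#' grouping vector (e.g. category or library).
#'
#' @param reads `GRanges` of aligned reads.
#' @param by Optional grouping vector of length `length(reads)`.
#' @param min_len,max_len Histogram support (18 and 36 nt).
#' @return Data frame with columns `length`, (optionally) `group`, and
#'   `count`.
#' @export
length_distribution <- function(reads, by = NULL, min_len = 18L,
                                max_len = 36L) {
  lens <- factor(width(reads), levels = seq.int(min_len, max_len))
  if (is.null(by)) {
    tab <- table(length = lens)
    return(data.frame(length = as.integer(names(tab)),
                      count = as.integer(tab)))
  }
  tab <- table(length = lens, group = by)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$length <- as.integer(as.character(df$length))
  names(df)[names(df) == "Freq"] <- "count"
  df
}

#' Per-library category accounting
#'
#' Summarizes the number (and fraction) of aligned reads falling in
#' each genomic category per library, plus a total column. Two counting
#' semantics are supported: `"partition"` assigns every read to exactly
#' one category under the priority order (counts sum to the aligned
#' total), while `"overlap"` counts a read in every annotation row it
#' overlaps (rows need not partition the total), the semantics of
#' per-annotation overlap summaries.
#'
#' @param reads `GRanges` of aligned reads with a `library` metadata
#'   column.
#' @param annotations An `AnnotationSet`.
#' @param mode `"partition"` (default) or `"overlap"`.
#' @param priority Priority order for partition mode (see
#'   [assign_category()]).
#' @param include_flagged Include out-of-length-range reads (default
#'   `FALSE`).
#' @return Data frame: rows `aligned`, `gene`, `repeat`, `intergenic`,
#'   `tRNA`, `ncRNA`; per library a `<lib>_count` and `<lib>_fraction`
#'   column plus `total_count` / `total_fraction`. Fractions use the
#'   per-library aligned-read totals as denominator.
#' @export
summary_table <- function(reads, annotations,
                          mode = c("partition", "overlap"),
                          priority = c("tRNA", "ncRNA", "repeat",
                                       "gene"),
                          include_flagged = FALSE) {
  mode <- match.arg(mode)
  if (!include_flagged && !is.null(mcols(reads)$flagged)) {
    reads <- reads[!mcols(reads)$flagged]
  }
  lib <- mcols(reads)$library
  if (is.null(lib)) lib <- rep("lib1", length(reads))
  libs <- sort(unique(lib))
  cats <- c("gene", "repeat", "intergenic", "tRNA", "ncRNA")
  count_one <- function(sel) {
    r <- reads[sel]
    if (mode == "partition") {
      asg <- assign_category(r, annotations, priority)
      tab <- table(asg)
      counts <- setNames(as.integer(tab[cats]), cats)
      counts[is.na(counts)] <- 0L
    } else {
      comp <- c(gene = "genes", "repeat" = "repeats", tRNA = "trnas",
                ncRNA = "ncrnas")
      counts <- vapply(cats, function(cat) {
        if (cat == "intergenic") {
          anywhere <- Reduce(`|`, lapply(comp, function(nm) {
            ann <- annotations[[nm]]
            if (is.null(ann) || length(ann) == 0L) {
              rep(FALSE, length(r))
            } else {
              overlapsAny(r, ann, ignore.strand = TRUE)
            }
          }))
          sum(!anywhere)
        } else {
          ann <- annotations[[comp[[cat]]]]
          if (is.null(ann) || length(ann) == 0L) {
            0L
          } else {
            sum(overlapsAny(r, ann, ignore.strand = TRUE))
          }
        }
      }, numeric(1))
    }
    c(aligned = length(r), counts)
  }
  mat <- vapply(libs, function(l) count_one(lib == l),
                numeric(length(cats) + 1L))
  mat <- cbind(mat, total = rowSums(mat))
  out <- data.frame(category = rownames(mat))
  for (j in colnames(mat)) {
    out[[paste0(j, "_count")]] <- as.integer(mat[, j])
    out[[paste0(j, "_fraction")]] <- mat[, j] / mat["aligned", j]
  }
  rownames(out) <- NULL
  out
}
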