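#' Run the full sRNA analysis pipeline
#'
#' Orchestrates all stages on a data bundle: read loading, category
#' and length profiling, locus clustering and candidate filtering, tRF
#' classification, TE coverage/expression/methylation statistics,
#' periodicity scan and region calling, and hairpin evaluation of
#' intergenic candidates. Writes every result as TSV/JSON plus a run
#' manifest with parameters, seed and output checksums; with identical
#' inputs, parameters and seed the outputs are identical.
#'
#' @param bundle Either a bundle list from [synth_generate()] or a
#'   directory written by [synth_write_bundle()].
#' @param out_dir Output directory.
#' @param seed Seed for the stochastic stages (hairpin empirical null).
#' @param params Named list of per-stage parameter overrides:
#'   `max_gap`, `min_reads`, `window`, `step`, `sig_frac`, `span`,
#'   `min_significant`, `n_perm`, `flank`, `backend`, `temperature`,
#'   `max_candidates`.
#' @return Invisibly, a list with the in-memory results of every stage
#'   and the manifest.
#' @export
run_all <- function(bundle, out_dir, seed = 1L, params = list()) {
  p <- utils::modifyList(list(
    max_gap = 100L, min_reads = 10L, window = 1000L, step = 100L,
    sig_frac = 0.75, span = 5000L, min_significant = 3L,
    n_perm = 200L, flank = 50L, backend = "auto", temperature = 24,
    max_candidates = 10L), params)
  if (is.character(bundle)) bundle <- read_bundle_dir(bundle)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- bundle$reads
  ann <- bundle$annotations
  res <- list(params = p, seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ctx("pipeline stage '%s' failed: %s", name,
               conditionMessage(e))
    })
  }
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## categories & length profiles
  res$summary <- stage("categories",
                       summary_table(reads, ann, mode = "partition"))
  tsv(res$summary, "summary_table.tsv")
  cat_assign <- assign_category(reads, ann)
  res$length_dist <- stage("lengths",
                           length_distribution(reads, by = cat_assign))
  tsv(res$length_dist, "length_distribution.tsv")

  ## loci
  res$loci <- stage("loci",
                    cluster_srna_loci(reads, max_gap = p$max_gap,
                                      min_reads = p$min_reads))
  tsv(loci_to_df(res$loci), "loci.tsv")
  res$candidates <- stage("candidates", {
    pile <- res$loci[mcols(res$loci)$distribution_class == "PILE"]
    filter_candidates(pile, ann)
  })
  tsv(loci_to_df(res$candidates), "candidates.tsv")

  ## tRFs
  res$trf <- stage("trf", {
    frag <- reads[overlapsAny(reads, ann$trnas, ignore.strand = TRUE) &
                    !mcols(reads)$flagged]
    if (length(frag) > 0L) {
      t <- classify_trf(frag, ann$trnas)
      t$read_id <- mcols(frag)$name[t$fragment]
      t
    } else NULL
  })
  if (!is.null(res$trf)) tsv(res$trf, "trf.tsv")

  ## TE statistics
  if (!is.null(ann$repeats)) {
    res$te_stats <- stage("te_stats", {
      te_expr <- NULL
      if (!is.null(bundle$expression)) {
        ex <- bundle$expression[bundle$expression$type == "TE", ,
                                drop = FALSE]
        te_expr <- ex$expression[match_regions(ann$repeats, ex)]
      }
      te_region_stats(ann$repeats, reads, probes = ann$methylation,
                      expression = te_expr)
    })
    tsv(res$te_stats, "te_stats.tsv")
    res$tests <- stage("association", {
      s <- res$te_stats
      association_tests(
        s$srna_rpkm,
        expr_class = if (!is.null(s$expression_class))
          s$expression_class else NULL,
        methylation = if (!is.null(s$methylation_level))
          s$methylation_level else NULL)
    })
    write_json(res$tests, file.path(out_dir, "association_tests.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE,
               force = TRUE)
  }

  ## periodicity (multimapper-reweighted coverage, per the method)
  res$windows <- stage("periodicity", {
    sl <- seqlengths(reads)
    if (length(sl) == 0L || any(is.na(sl))) {
      sl <- setNames(width(bundle$genome), names(bundle$genome))
    }
    cov <- compute_coverage(reads, mode = "reweighted",
                            seqlengths = sl)
    scan_periodicity(cov, window = p$window, step = p$step,
                     sig_frac = p$sig_frac)
  })
  tsv(res$windows, "period_windows.tsv")
  res$periodic_regions <- stage("periodic_regions",
    call_periodic_regions(res$windows, span = p$span,
                          min_significant = p$min_significant))
  tsv(res$periodic_regions, "periodic_regions.tsv")
  if (!is.null(ann$methylation)) {
    hmr <- methylated_regions(ann$methylation)
    res$hmr_overlap <- stage("hmr_overlap",
      hmr_overlap(res$periodic_regions, hmr, loci = res$loci))
    write_json(res$hmr_overlap, file.path(out_dir, "hmr_overlap.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    warn_ctx("no methylation probes: HMR overlap stage skipped")
  }

  ## hairpin evaluation of intergenic-novel candidates
  res$hairpins <- stage("hairpin", {
    cand <- res$candidates
    cand <- cand[mcols(cand)$pass_all &
                   mcols(cand)$candidate_type == "intergenic-novel"]
    cand <- head(cand, p$max_candidates)
    if (length(cand) == 0L) {
      list()
    } else {
      lapply(seq_along(cand), function(i) {
        h <- evaluate_hairpin(cand[i], reads, bundle$genome,
                              flank = p$flank, n_perm = p$n_perm,
                              seed = seed + i, backend = p$backend,
                              temperature = p$temperature)
        h[c("structure", "mfe", "empirical_p", "significant",
            "mature_local", "verdict", "backend", "seed")]
      })
    }
  })
  write_json(res$hairpins, file.path(out_dir, "hairpins.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE,
             force = TRUE)

  ## manifest
  outs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  res$manifest <- list(
    package = "srnascape",
    version = as.character(utils::packageVersion("srnascape")),
    seed = seed, params = p,
    outputs = as.list(tools::md5sum(file.path(out_dir, outs))))
  names(res$manifest$outputs) <- outs
  write_json(res$manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

loci_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr), end = end(gr),
                   strand = as.character(strand(gr)),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(mcols(gr)))
}

match_regions <- function(gr, df) {
  key_gr <- paste(as.character(seqnames(gr)), start(gr), end(gr))
  key_df <- paste(df$chrom, df$start, df$end)
  match(key_gr, key_df)
}

# Merge methylated probe calls into highly methylated regions: probes
# called methylated within merge_gap of each other, at least min_probes
# per region.
methylated_regions <- function(probes, merge_gap = 200L,
                               min_probes = 5L) {
  m <- probes[mcols(probes)$call > 0]
  if (length(m) == 0L) return(GRanges())
  reg <- reduce(granges(m), min.gapwidth = merge_gap,
                ignore.strand = TRUE)
  reg[countOverlaps(reg, m, ignore.strand = TRUE) >= min_probes]
}

# Read a bundle directory written by synth_write_bundle() back into
# the in-memory layout run_all() expects.
read_bundle_dir <- function(dir) {
  genome <- readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  bed_files <- list.files(dir, pattern = "^reads_.*\\.bed$",
                          full.names = TRUE)
  reads <- do.call(c, lapply(bed_files, function(f) {
    lab <- sub("^reads_", "", sub("\\.bed$", "", basename(f)))
    lab <- sub("^minus_", "-", lab)
    load_alignments(f, library_label = lab, genome = genome)
  }))
  opt <- function(f) if (file.exists(file.path(dir, f)))
    file.path(dir, f) else NULL
  ann <- load_annotations(
    genome = genome, genes = opt("genes.gff3"),
    repeats = opt("repeats.gff3"), ncrnas = opt("ncrnas.gff3"),
    trnas = opt("trna.tsv"), methylation = opt("methylation.bed"))
  expression <- if (file.exists(file.path(dir, "expression.tsv"))) {
    read.table(file.path(dir, "expression.tsv"), header = TRUE,
               sep = "\t", stringsAsFactors = FALSE)
  } else NULL
  list(genome = genome, reads = reads, annotations = ann,
       expression = expression)
}
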