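#' Configuration for the synthetic-data generator
#'
#' Returns the default generator configuration, optionally overridden.
#' The defaults emulate the hallmark sRNA populations of a diatom-style
#' small-RNA landscape: strand-specific sequence piles; an intergenic
#' locus of two overlapping 24/25 nt fragments with a central coverage
#' plateau; a U2-snRNA-like region with a deep 3' pile (26,000 reads)
#' and a shallow 5' pile (1,200 reads); tRNA genes emitting a mix of
#' tRF classes with genome-templated 3' CCA; transposable elements
#' covered on both strands by 25-30 nt reads with a 60% 5'-U bias,
#' methylated and silenced; highly methylated regions with read piles
#' spaced 180 nt apart; and a uniform degradation background.
#'
#' @param seed RNG seed; the seed fully determines the bundle.
#' @param ... Named overrides of any top-level default.
#' @return A configuration list.
#' @export
synth_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    n_chrom = 2L,
    chrom_len = 80000L,
    gc = 0.48,
    libraries = c("NL", "HL", "LL", "D", "-Fe"),
    read_len_range = c(18L, 36L),
    pile = list(n = 3L, length = 24L, depth = 2000L),
    plateau = list(region_len = 85L, frag_lens = c(24L, 25L),
                   frag_offsets = c(18L, 30L), depth = 5000L),
    u2 = list(region_len = 226L, depth3 = 26000L, depth5 = 1200L,
              len3 = 23L, len5 = 21L),
    trna = list(n = 4L, gene_len = 72L, depth = 10000L,
                class_probs = c("3p_short" = 0.45,
                                "dloop_anticodon" = 0.15,
                                "3p_long" = 0.15, "5p_long" = 0.15,
                                "half_tRNA" = 0.10),
                cca_rate = 0.95),
    te = list(lengths = rep(c(2000L, 1200L, 800L, 3500L), 5L),
              families = rep(c("Copia", "Copia", "PiggyBac",
                               "Blackbeard"), 5L),
              methylated = rep(c(TRUE, FALSE, FALSE, FALSE), 5L),
              depths = NULL,  # derived below when NULL
              meth_depth_per_nt = 1.5, unmeth_depth_per_nt = 0.04,
              u_bias = 0.6, len_range = c(25L, 30L),
              probe_spacing = 60L, meth_call_rate = 0.9,
              unmeth_call_rate = 0.1, multimapper_frac = 0.05),
    hmr = list(n = 2L, span = 5000L, period = 180, pile_width = 25L,
               pile_depth = 30, jitter_sd = 5,
               len_range = c(25L, 30L), probe_spacing = 50L),
    genes = list(n = 8L, length = 1500L, n_methylated = 2L,
                 meth_depth = 400L),
    background = list(rate = 0.002, len_geom_p = 0.3)
  )
  utils::modifyList(cfg, list(...))
}

random_genome <- function(n_chrom, chrom_len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(names(p), chrom_len, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  genome <- DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(n_chrom))
  genome
}

# sequential feature placement: round-robin over chromosomes with a
# fixed inter-feature gap so planted loci never link by read clustering
make_allocator <- function(n_chrom, chrom_len, gap = 1500L,
                           margin = 600L) {
  cursors <- rep(margin, n_chrom)
  chrom_i <- 0L
  function(len) {
    for (try in seq_len(n_chrom)) {
      chrom_i <<- (chrom_i %% n_chrom) + 1L
      s <- cursors[chrom_i]
      if (s + len - 1L <= chrom_len - margin) {
        cursors[chrom_i] <<- s + len + gap
        return(list(chrom = paste0("chr", chrom_i), start = s,
                    end = s + len - 1L))
      }
    }
    stop_ctx("features exceed the genome: cannot place a %d nt feature",
             len)
  }
}

genome_subseq <- function(genome, chrom, s, e, strand = "+") {
  x <- subseq(genome[[chrom]], s, e)
  if (strand == "-") x <- reverseComplement(x)
  as.character(x)
}

# vectorized extraction of many read sequences from one chromosome
# string; minus-strand reads are reverse-complemented in one batch
extract_seqs <- function(chrom_string, starts, ends, strands) {
  seqs <- substring(chrom_string, starts, ends)
  minus <- strands == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      reverseComplement(DNAStringSet(seqs[minus])))
  }
  seqs
}

#' Generate a synthetic sRNA data bundle
#'
#' Builds a toy genome, annotations, methylation probe track,
#' expression table and read set with the statistical structure the
#' pipeline stages assume, plus truth tables recording every planted
#' feature. Identical seeds give identical bundles.
#'
#' @param config From [synth_config()].
#' @return List with elements `genome` (`DNAStringSet`), `reads`
#'   (`GRanges` with `seq`, `multiplicity`, `weight`, `library`,
#'   `flagged`), `annotations` (`AnnotationSet`), `expression` (data
#'   frame), `truth` (list of data frames `loci`, `trf`, `periodic`),
#'   and `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  set.seed(config$seed)
  genome <- random_genome(config$n_chrom, config$chrom_len, config$gc)
  alloc <- make_allocator(config$n_chrom, config$chrom_len)
  reads <- list()
  truth_loci <- list()
  truth_trf <- NULL
  truth_periodic <- list()
  genes <- list(); repeats <- list(); ncrnas <- list()
  trna_rows <- list(); probes <- list(); expr <- list()

  add_reads <- function(chrom, starts, lens, strands, seqs, mult = 1L) {
    data.frame(chrom = chrom, start = starts,
               end = starts + lens - 1L, strand = strands, seq = seqs,
               multiplicity = mult, stringsAsFactors = FALSE)
  }

  ## --- strand-specific sequence piles -------------------------------
  for (i in seq_len(config$pile$n)) {
    len <- config$pile$length
    loc <- alloc(len)
    strand <- sample(c("+", "-"), 1L)
    s <- genome_subseq(genome, loc$chrom, loc$start, loc$end, strand)
    d <- config$pile$depth
    reads[[length(reads) + 1L]] <-
      add_reads(loc$chrom, rep(loc$start, d), rep(len, d),
                rep(strand, d), rep(s, d))
    truth_loci[[length(truth_loci) + 1L]] <-
      data.frame(feature = paste0("pile", i), type = "pile",
                 chrom = loc$chrom, start = loc$start, end = loc$end,
                 class = "PILE", stringsAsFactors = FALSE)
  }

  ## --- intergenic plateau locus (two overlapping fragments) ---------
  pl <- config$plateau
  loc <- alloc(pl$region_len)
  d <- pl$depth
  which_frag <- sample(1:2, d, replace = TRUE)
  fstarts <- loc$start + pl$frag_offsets[which_frag]
  flens <- pl$frag_lens[which_frag]
  fseqs <- vapply(unique(which_frag), function(k) {
    genome_subseq(genome, loc$chrom, loc$start + pl$frag_offsets[k],
                  loc$start + pl$frag_offsets[k] + pl$frag_lens[k] - 1L)
  }, character(1))[which_frag]
  reads[[length(reads) + 1L]] <-
    add_reads(loc$chrom, fstarts, flens, rep("+", d), fseqs)
  truth_loci[[length(truth_loci) + 1L]] <-
    data.frame(feature = "plateau", type = "plateau", chrom = loc$chrom,
               start = loc$start, end = loc$end, class = "DISTRIBUTED",
               stringsAsFactors = FALSE)

  ## --- U2-like locus: deep 3' pile, shallow 5' pile -----------------
  u2 <- config$u2
  loc <- alloc(u2$region_len)
  s5 <- loc$start
  s3 <- loc$end - u2$len3 + 1L
  seq5 <- genome_subseq(genome, loc$chrom, s5, s5 + u2$len5 - 1L)
  seq3 <- genome_subseq(genome, loc$chrom, s3, loc$end)
  reads[[length(reads) + 1L]] <- rbind(
    add_reads(loc$chrom, rep(s3, u2$depth3), rep(u2$len3, u2$depth3),
              rep("+", u2$depth3), rep(seq3, u2$depth3)),
    add_reads(loc$chrom, rep(s5, u2$depth5), rep(u2$len5, u2$depth5),
              rep("+", u2$depth5), rep(seq5, u2$depth5)))
  ncrnas[[length(ncrnas) + 1L]] <-
    data.frame(chrom = loc$chrom, start = loc$start, end = loc$end,
               strand = "+", type = "snRNA", name = "U2-like",
               stringsAsFactors = FALSE)
  truth_loci[[length(truth_loci) + 1L]] <-
    data.frame(feature = "u2", type = "u2", chrom = loc$chrom,
               start = loc$start, end = loc$end, class = "PILE",
               stringsAsFactors = FALSE)

  ## --- tRNA genes and tRF reads -------------------------------------
  tr <- config$trna
  # arm layout in 1-based tRNA-relative coordinates (gene_len = 72):
  arm <- list(acceptor = c(66L, 72L), dloop = c(14L, 21L),
              acloop = c(32L, 38L), tloop = c(54L, 60L))
  isotypes <- c("Gly", "Glu", "Asp", "Pro", "Ala", "Lys")
  anticodons <- c("GCC", "GAG", "CAG", "CCT", "AGC", "CTT")
  trna_locs <- vector("list", tr$n)
  for (i in seq_len(tr$n)) {
    loc <- alloc(tr$gene_len)
    strand <- c("+", "-")[(i %% 2L) + 1L]
    # genome-templated CCA at the mature 3' terminus
    mature <- paste0(
      paste(sample(c("A", "C", "G", "T"), tr$gene_len - 3L,
                   replace = TRUE), collapse = ""), "CCA")
    gseq <- if (strand == "-") {
      as.character(reverseComplement(DNAString(mature)))
    } else mature
    subseq(genome[[loc$chrom]], loc$start, loc$end) <- DNAString(gseq)
    arm_genomic <- function(a) {
      if (strand == "-") {
        c(loc$end - a[2] + 1L, loc$end - a[1] + 1L)
      } else {
        c(loc$start + a[1] - 1L, loc$start + a[2] - 1L)
      }
    }
    acc <- arm_genomic(arm$acceptor); dlp <- arm_genomic(arm$dloop)
    acl <- arm_genomic(arm$acloop); tlp <- arm_genomic(arm$tloop)
    trna_rows[[i]] <- data.frame(
      trna_id = paste0("tRNA-", isotypes[i], "-", anticodons[i]),
      chrom = loc$chrom, start = loc$start, end = loc$end,
      strand = strand, isotype = isotypes[i],
      anticodon = anticodons[i],
      acceptor_start = acc[1], acceptor_end = acc[2],
      dloop_start = dlp[1], dloop_end = dlp[2],
      anticodon_start = acl[1], anticodon_end = acl[2],
      tloop_start = tlp[1], tloop_end = tlp[2],
      stringsAsFactors = FALSE)
    trna_locs[[i]] <- list(loc = loc, strand = strand, mature = mature)
    truth_loci[[length(truth_loci) + 1L]] <-
      data.frame(feature = trna_rows[[i]]$trna_id, type = "trna",
                 chrom = loc$chrom, start = loc$start, end = loc$end,
                 class = "DISTRIBUTED", stringsAsFactors = FALSE)
  }
  # genome is final from here on; keep per-chromosome character
  # strings for fast vectorized sequence extraction
  gchar <- as.character(genome)
  # sample tRF reads
  d <- tr$depth
  which_trna <- sample.int(tr$n, d, replace = TRUE)
  classes <- sample(names(tr$class_probs), d, replace = TRUE,
                    prob = tr$class_probs)
  gl <- tr$gene_len
  rel_s <- integer(d); rel_e <- integer(d); cca_truth <- character(d)
  for (j in seq_len(d)) {
    cl <- classes[j]
    if (cl == "3p_short") {
      len <- sample(18:20, 1L)
      if (runif(1) < tr$cca_rate) {
        rel_e[j] <- gl          # ends at terminus, templated CCA
        cca_truth[j] <- "present"
      } else {
        rel_e[j] <- gl - 3L     # trimmed before the CCA
        cca_truth[j] <- "absent"
      }
      rel_s[j] <- rel_e[j] - len + 1L
    } else if (cl == "3p_long") {
      len <- sample(30:34, 1L)
      rel_e[j] <- gl - 3L       # 3'-anchored but CCA-less
      rel_s[j] <- rel_e[j] - len + 1L
      cca_truth[j] <- "absent"
    } else if (cl == "5p_long") {
      rel_s[j] <- sample(1:2, 1L)
      len <- if (rel_s[j] == 1L) sample(30:31, 1L) else 30L
      rel_e[j] <- rel_s[j] + len - 1L
      cca_truth[j] <- "not_applicable"
    } else if (cl == "half_tRNA") {
      rel_s[j] <- 1L
      rel_e[j] <- sample(arm$acloop[1]:min(arm$acloop[2], 36L), 1L)
      cca_truth[j] <- "not_applicable"
    } else {                    # dloop_anticodon
      len <- sample(18:20, 1L)
      rel_s[j] <- if (runif(1) < 0.5) sample(12:16, 1L) else
        sample(29:32, 1L)
      rel_e[j] <- rel_s[j] + len - 1L
      cca_truth[j] <- "not_applicable"
    }
  }
  t_mature <- vapply(trna_locs, function(tl) tl$mature, character(1))
  t_strand <- vapply(trna_locs, function(tl) tl$strand, character(1))
  t_chrom <- vapply(trna_locs, function(tl) tl$loc$chrom, character(1))
  t_start <- vapply(trna_locs, function(tl) tl$loc$start, integer(1))
  t_end <- vapply(trna_locs, function(tl) tl$loc$end, integer(1))
  mseq <- substring(t_mature[which_trna], rel_s, rel_e)
  minus <- t_strand[which_trna] == "-"
  gs <- ifelse(minus, t_end[which_trna] - rel_e + 1L,
               t_start[which_trna] + rel_s - 1L)
  ge <- ifelse(minus, t_end[which_trna] - rel_s + 1L,
               t_start[which_trna] + rel_e - 1L)
  trf_block <- add_reads(t_chrom[which_trna], gs, ge - gs + 1L,
                         t_strand[which_trna], mseq)
  # row offset of the tRF block within the final combined read table,
  # used below to key truth rows to final read ids
  trf_row_offset <- sum(vapply(reads, nrow, integer(1)))
  truth_trf <- data.frame(
    trna_id = vapply(which_trna, function(i) trna_rows[[i]]$trna_id,
                     character(1)),
    trf_class = classes, cca = cca_truth, stringsAsFactors = FALSE)
  reads[[length(reads) + 1L]] <- trf_block

  ## --- TE regions: both-strand 25-30 nt coverage, 5'-U bias ---------
  te <- config$te
  n_te <- length(te$lengths)
  if (is.null(te$depths)) {
    # methylated/silenced TEs carry dense sRNA coverage, expressed
    # ones only background-level coverage
    te$depths <- round(te$lengths *
                         ifelse(te$methylated, te$meth_depth_per_nt,
                                te$unmeth_depth_per_nt))
  }
  te_locs <- vector("list", n_te)
  for (i in seq_len(n_te)) {
    loc <- alloc(te$lengths[i])
    te_locs[[i]] <- loc
    repeats[[length(repeats) + 1L]] <-
      data.frame(chrom = loc$chrom, start = loc$start, end = loc$end,
                 strand = "+", family = te$families[i],
                 name = paste0("TE", i), stringsAsFactors = FALSE)
    truth_loci[[length(truth_loci) + 1L]] <-
      data.frame(feature = paste0("TE", i), type = "te",
                 chrom = loc$chrom, start = loc$start, end = loc$end,
                 class = "DISTRIBUTED", stringsAsFactors = FALSE)
  }
  te_read_block <- function(i, depth, mult = 1L) {
    loc <- te_locs[[i]]
    lens <- sample(te$len_range[1]:te$len_range[2], depth,
                   replace = TRUE)
    starts <- loc$start +
      vapply(lens, function(l) {
        sample.int(te$lengths[i] - l + 1L, 1L) - 1L
      }, integer(1))
    strands <- sample(c("+", "-"), depth, replace = TRUE)
    seqs <- extract_seqs(gchar[[loc$chrom]], starts,
                         starts + lens - 1L, strands)
    # impose the 5' first-base bias on the read sequence
    first <- ifelse(runif(depth) < te$u_bias, "T",
                    sample(c("A", "C", "G"), depth, replace = TRUE))
    seqs <- paste0(first, substring(seqs, 2L))
    add_reads(loc$chrom, starts, lens, strands, seqs, mult)
  }
  for (i in seq_len(n_te)) {
    depth <- te$depths[i]
    n_multi <- if (n_te >= 2L && i <= 2L) {
      round(te$multimapper_frac * depth)
    } else 0L
    reads[[length(reads) + 1L]] <- te_read_block(i, depth - n_multi)
    if (n_multi > 0L) {
      # multimappers: the same read reported at both Copia copies
      blk <- te_read_block(i, n_multi, mult = 2L)
      other <- if (i == 1L) 2L else 1L
      off <- blk$start - te_locs[[i]]$start
      fit <- off + (blk$end - blk$start) < te$lengths[other]
      dup <- blk[fit, , drop = FALSE]
      dup$chrom <- te_locs[[other]]$chrom
      shift <- te_locs[[other]]$start - te_locs[[i]]$start
      dup$start <- dup$start + shift
      dup$end <- dup$end + shift
      blk$multiplicity[!fit] <- 1L
      reads[[length(reads) + 1L]] <- rbind(blk, dup)
    }
  }

  ## --- HMR loci with periodic pile placement ------------------------
  hm <- config$hmr
  for (i in seq_len(hm$n)) {
    loc <- alloc(hm$span)
    centers <- seq(loc$start, loc$end - hm$pile_width, by = hm$period)
    centers <- centers + round(rnorm(length(centers), 0, hm$jitter_sd))
    blocks <- lapply(centers, function(p) {
      depth <- rpois(1L, hm$pile_depth)
      if (depth == 0L) return(NULL)
      lens <- sample(hm$len_range[1]:hm$len_range[2], depth,
                     replace = TRUE)
      starts <- pmax(1L, p + sample(-3:3, depth, replace = TRUE))
      strands <- sample(c("+", "-"), depth, replace = TRUE)
      seqs <- extract_seqs(gchar[[loc$chrom]], starts,
                           starts + lens - 1L, strands)
      add_reads(loc$chrom, starts, lens, strands, seqs)
    })
    reads[[length(reads) + 1L]] <-
      do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
    truth_periodic[[length(truth_periodic) + 1L]] <-
      data.frame(feature = paste0("HMR", i), chrom = loc$chrom,
                 start = loc$start, end = loc$end, period = hm$period,
                 stringsAsFactors = FALSE)
    truth_loci[[length(truth_loci) + 1L]] <-
      data.frame(feature = paste0("HMR", i), type = "hmr",
                 chrom = loc$chrom, start = loc$start, end = loc$end,
                 class = "DISTRIBUTED", stringsAsFactors = FALSE)
  }

  ## --- genes, expression, methylation -------------------------------
  gn <- config$genes
  gene_locs <- vector("list", gn$n)
  meth_gene <- seq_len(gn$n) <= gn$n_methylated
  for (i in seq_len(gn$n)) {
    loc <- alloc(gn$length)
    gene_locs[[i]] <- loc
    genes[[length(genes) + 1L]] <-
      data.frame(chrom = loc$chrom, start = loc$start, end = loc$end,
                 strand = sample(c("+", "-"), 1L),
                 name = paste0("gene", i), stringsAsFactors = FALSE)
    if (meth_gene[i]) {
      # methylated genes carry TE-style both-strand read coverage
      depth <- gn$meth_depth
      lens <- sample(25:30, depth, replace = TRUE)
      starts <- loc$start +
        vapply(lens, function(l) {
          sample.int(gn$length - l + 1L, 1L) - 1L
        }, integer(1))
      strands <- sample(c("+", "-"), depth, replace = TRUE)
      seqs <- extract_seqs(gchar[[loc$chrom]], starts,
                           starts + lens - 1L, strands)
      reads[[length(reads) + 1L]] <-
        add_reads(loc$chrom, starts, lens, strands, seqs)
      truth_loci[[length(truth_loci) + 1L]] <-
        data.frame(feature = paste0("gene", i), type = "gene",
                   chrom = loc$chrom, start = loc$start, end = loc$end,
                   class = "DISTRIBUTED", stringsAsFactors = FALSE)
    }
  }
  # expression: methylated/silenced features low, others log-normal
  gene_expr <- ifelse(meth_gene, runif(gn$n, 0.01, 0.2),
                      exp(rnorm(gn$n, 3, 1)))
  expr[[1L]] <- data.frame(
    id = paste0("gene", seq_len(gn$n)), type = "gene",
    chrom = vapply(gene_locs, function(l) l$chrom, character(1)),
    start = vapply(gene_locs, function(l) l$start, integer(1)),
    end = vapply(gene_locs, function(l) l$end, integer(1)),
    expression = gene_expr, stringsAsFactors = FALSE)
  te_expr <- ifelse(te$methylated, runif(n_te, 0.01, 0.2),
                    exp(rnorm(n_te, 3, 1)))
  expr[[2L]] <- data.frame(
    id = paste0("TE", seq_len(n_te)), type = "TE",
    chrom = vapply(te_locs, function(l) l$chrom, character(1)),
    start = vapply(te_locs, function(l) l$start, integer(1)),
    end = vapply(te_locs, function(l) l$end, integer(1)),
    expression = te_expr, stringsAsFactors = FALSE)

  # methylation probes: dense over TEs/HMRs/methylated genes, sparse
  # background elsewhere
  probe_block <- function(chrom, s, e, spacing, call_rate) {
    pos <- seq(s, e, by = spacing)
    data.frame(chrom = chrom, start = pos, end = pos + 1L,
               call = as.integer(runif(length(pos)) < call_rate),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_te)) {
    loc <- te_locs[[i]]
    rate <- if (te$methylated[i]) te$meth_call_rate else
      te$unmeth_call_rate
    probes[[length(probes) + 1L]] <-
      probe_block(loc$chrom, loc$start, loc$end, te$probe_spacing,
                  rate)
  }
  for (tp in truth_periodic) {
    probes[[length(probes) + 1L]] <-
      probe_block(tp$chrom, tp$start, tp$end, hm$probe_spacing, 0.9)
  }
  for (i in which(meth_gene)) {
    loc <- gene_locs[[i]]
    probes[[length(probes) + 1L]] <-
      probe_block(loc$chrom, loc$start, loc$end, 60L, 0.85)
  }
  for (ch in names(genome)) {
    probes[[length(probes) + 1L]] <-
      probe_block(ch, 997L, config$chrom_len - 997L, 997L, 0.05)
  }

  ## --- degradation background ---------------------------------------
  bg <- config$background
  total_len <- config$n_chrom * config$chrom_len
  n_bg <- rpois(1L, bg$rate * total_len)
  bg_chrom <- sample(names(genome), n_bg, replace = TRUE)
  bg_len <- pmin(config$read_len_range[1] +
                   rgeom(n_bg, bg$len_geom_p),
                 config$read_len_range[2])
  bg_start <- vapply(seq_len(n_bg), function(j) {
    sample.int(config$chrom_len - bg_len[j], 1L)
  }, integer(1))
  bg_seq <- character(n_bg)
  for (ch in unique(bg_chrom)) {
    ii <- which(bg_chrom == ch)
    bg_seq[ii] <- substring(gchar[[ch]], bg_start[ii],
                            bg_start[ii] + bg_len[ii] - 1L)
  }
  reads[[length(reads) + 1L]] <-
    add_reads(bg_chrom, bg_start, bg_len,
              sample(c("+", "-"), n_bg, replace = TRUE), bg_seq)

  ## --- assemble ------------------------------------------------------
  rd <- do.call(rbind, reads)
  rd$library <- sample(config$libraries, nrow(rd), replace = TRUE)
  rd$read_id <- paste0("r", seq_len(nrow(rd)))
  truth_trf <- cbind(
    data.frame(read_id = rd$read_id[trf_row_offset +
                                      seq_len(nrow(truth_trf))]),
    truth_trf)
  gr <- GRanges(rd$chrom, IRanges(rd$start, rd$end), strand = rd$strand,
                seqinfo = Seqinfo(names(genome), width(genome)))
  mcols(gr) <- S4Vectors::DataFrame(
    seq = rd$seq, multiplicity = rd$multiplicity,
    weight = 1 / rd$multiplicity, library = rd$library,
    name = rd$read_id)
  mcols(gr)$flagged <- width(gr) < config$read_len_range[1] |
    width(gr) > config$read_len_range[2]
  ann <- load_annotations(
    genome = genome,
    genes = df_to_gr(do.call(rbind, genes), genome, type = "gene"),
    repeats = df_to_gr(do.call(rbind, repeats), genome,
                       type = "repeat_region"),
    ncrnas = df_to_gr(do.call(rbind, ncrnas), genome),
    trnas = {
      tdf <- do.call(rbind, trna_rows)
      tgr <- GRanges(tdf$chrom, IRanges(tdf$start, tdf$end),
                     strand = tdf$strand)
      mcols(tgr) <- tdf[, c("trna_id", "isotype", "anticodon",
                            trna_arm_cols)]
      tgr
    },
    methylation = {
      pdf <- do.call(rbind, probes)
      GRanges(pdf$chrom, IRanges(pdf$start, pdf$end), call = pdf$call)
    })
  list(genome = genome, reads = gr, annotations = ann,
       expression = do.call(rbind, expr),
       truth = list(loci = do.call(rbind, truth_loci),
                    trf = truth_trf,
                    periodic = do.call(rbind, truth_periodic)),
       config = config)
}

df_to_gr <- function(df, genome, type = NULL) {
  if (is.null(df) || nrow(df) == 0L) return(NULL)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                strand = if ("strand" %in% names(df)) df$strand else "*")
  keep <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  mcols(gr) <- df[, keep, drop = FALSE]
  if (!is.null(type)) mcols(gr)$type <- type
  gr
}

#' Synthetic periodic coverage for a highly methylated region
#'
#' Direct coverage-vector emulation of the HMR read placement model:
#' read piles of width `pile_width` spaced `period` nt apart (with
#' Gaussian position jitter and Poisson pile depths) over a `span` nt
#' region, embedded in `flank` nt of sparse background on either side.
#' Defaults match [synth_config()]'s HMR block.
#'
#' @param period Pile spacing in nt (default 180).
#' @param span HMR length in nt (default 5000).
#' @param pile_width Read pile width in nt (default 25).
#' @param pile_depth Mean pile depth (default 30).
#' @param jitter_sd Gaussian jitter of pile positions in nt (default 5).
#' @param flank Flat background flank on each side in nt (default 2500).
#' @param background_rate Mean background coverage per position
#'   (default 0.2).
#' @param seed Optional RNG seed.
#' @return Numeric coverage vector of length `span + 2 * flank`.
#' @export
synth_hmr_coverage <- function(period = 180, span = 5000L,
                               pile_width = 25L, pile_depth = 30,
                               jitter_sd = 5, flank = 2500L,
                               background_rate = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- span + 2L * flank
  cov <- rpois(n, background_rate)
  centers <- seq(flank + 1L, flank + span - pile_width, by = period)
  centers <- centers + round(rnorm(length(centers), 0, jitter_sd))
  for (p in centers) {
    depth <- rpois(1L, pile_depth)
    s <- max(1L, p)
    e <- min(n, p + pile_width - 1L)
    if (s <= e) cov[s:e] <- cov[s:e] + depth
  }
  as.numeric(cov)
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes the bundle as `genome.fa`, per-library read BEDs
#' (`reads_<lib>.bed`, the package's 7-column dialect), `genes.gff3`,
#' `repeats.gff3`, `ncrnas.gff3`, `trna.tsv`, `methylation.bed`,
#' `expression.tsv` and truth tables. With a fixed config seed the
#' bundle is byte-identical across runs.
#'
#' @param bundle From [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
synth_write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  rd <- bundle$reads
  lib <- mcols(rd)$library
  for (l in unique(lib)) {
    r <- rd[lib == l]
    df <- data.frame(as.character(seqnames(r)), start(r) - 1L, end(r),
                     mcols(r)$name, mcols(r)$multiplicity,
                     as.character(strand(r)), mcols(r)$seq)
    fname <- paste0("reads_", gsub("^-", "minus_", l), ".bed")
    write.table(df, file.path(dir, fname), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  ann <- bundle$annotations
  export_gff3 <- function(gr, path) {
    if (!is.null(gr)) rtracklayer::export(gr, path, format = "gff3")
  }
  export_gff3(ann$genes, file.path(dir, "genes.gff3"))
  export_gff3(ann$repeats, file.path(dir, "repeats.gff3"))
  export_gff3(ann$ncrnas, file.path(dir, "ncrnas.gff3"))
  tdf <- as.data.frame(mcols(ann$trnas))
  tdf <- cbind(data.frame(chrom = as.character(seqnames(ann$trnas)),
                          start = start(ann$trnas),
                          end = end(ann$trnas),
                          strand = as.character(strand(ann$trnas))),
               tdf)
  tdf <- tdf[, c("trna_id", "chrom", "start", "end", "strand",
                 "isotype", "anticodon", trna_arm_cols)]
  write.table(tdf, file.path(dir, "trna.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mp <- ann$methylation
  write.table(data.frame(as.character(seqnames(mp)), start(mp) - 1L,
                         end(mp), ".", mcols(mp)$call, "."),
              file.path(dir, "methylation.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(bundle$expression, file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("loci", "trf", "periodic")) {
    write.table(bundle$truth[[nm]],
                file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
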