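# Shared fixtures and independent brute-force oracles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(S4Vectors)
  library(IRanges)
})

# Construct a read GRanges with the metadata layout load_alignments()
# produces.
make_reads <- function(chrom, start, width, strand = "+",
                       seq = NA_character_, mult = 1L, lib = "NL",
                       flagged = FALSE) {
  n <- max(length(chrom), length(start), length(width), length(strand))
  gr <- GRanges(rep_len(chrom, n),
                IRanges(rep_len(start, n), width = rep_len(width, n)),
                strand = rep_len(strand, n))
  mcols(gr) <- S4Vectors::DataFrame(seq = rep_len(seq, n),
                         multiplicity = rep_len(as.integer(mult), n),
                         weight = 1 / rep_len(as.integer(mult), n),
                         library = rep_len(lib, n),
                         name = paste0("r", seq_len(n)),
                         flagged = rep_len(flagged, n))
  gr
}

# Brute-force O(n^2) discrete Fourier transform magnitudes (k = 1..n/2).
brute_dft_mags <- function(x) {
  n <- length(x)
  idx <- seq_len(n) - 1L
  vapply(seq_len(floor(n / 2)), function(k) {
    Mod(sum(x * exp(-2i * pi * k * idx / n)))
  }, numeric(1))
}

# Brute-force single-linkage clustering of intervals: reads are linked
# iff their gap (1-based closed coordinates) is < max_gap; returns the
# component id per read.
brute_single_linkage <- function(start, end, max_gap) {
  n <- length(start)
  gap <- function(i, j) {
    max(0L, max(start[i], start[j]) - min(end[i], end[j]) - 1L)
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] && gap(i, j) < max_gap) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Exact one-sided Mann-Whitney p-value, P(U >= U_obs), by enumeration
# of all group labelings (tie-free data).
brute_mw_greater <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_stat(x, y)
  vals <- c(x, y)
  picks <- utils::combn(length(vals), length(x))
  us <- apply(picks, 2, function(ii) u_stat(vals[ii], vals[-ii]))
  mean(us >= u_obs)
}

# Minimal tRNA gene model on one chromosome: 72 nt gene, 1-based
# relative arms acceptor 66-72 (3' terminus = gene end, genome-
# templated CCA at 70-72), D loop 14-21, anticodon loop 32-38,
# T loop 54-60.
make_trna_model <- function(chrom = "chr1", start = 1000L,
                            strand = "+", id = "tRNA-Gly-GCC") {
  gene_len <- 72L
  end <- start + gene_len - 1L
  rel <- function(a, b) {
    if (strand == "-") c(end - b + 1L, end - a + 1L) else
      c(start + a - 1L, start + b - 1L)
  }
  acc <- rel(66L, 72L); dlp <- rel(14L, 21L)
  acl <- rel(32L, 38L); tlp <- rel(54L, 60L)
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr) <- S4Vectors::DataFrame(trna_id = id, isotype = "Gly",
                         anticodon = "GCC",
                         acceptor_start = acc[1], acceptor_end = acc[2],
                         dloop_start = dlp[1], dloop_end = dlp[2],
                         anticodon_start = acl[1],
                         anticodon_end = acl[2],
                         tloop_start = tlp[1], tloop_end = tlp[2])
  gr
}

# Fragment GRanges at a tRNA-relative position (1-based within gene).
trna_fragment <- function(trna, rel_start, rel_end, seq = NA_character_) {
  st <- as.character(strand(trna))
  if (st == "-") {
    gs <- end(trna) - rel_end + 1L
    ge <- end(trna) - rel_start + 1L
  } else {
    gs <- start(trna) + rel_start - 1L
    ge <- start(trna) + rel_end - 1L
  }
  make_reads(as.character(seqnames(trna)), gs, ge - gs + 1L,
             strand = st, seq = seq)
}

random_test_genome <- function(seed, n_chrom = 1L, len = 10000L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
  g <- DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}
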