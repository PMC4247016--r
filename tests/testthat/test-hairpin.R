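planted_hairpin_genome <- function(seed = 7, len = 20000L,
                                   arm = 30L, at = 5001L) {
  set.seed(seed)
  g <- random_test_genome(seed, len = len)
  arm_seq <- paste(sample(c("A", "C", "G", "T"), arm, TRUE),
                   collapse = "")
  hp <- paste0(arm_seq, "TTCGAATT",
               as.character(reverseComplement(DNAString(arm_seq))))
  subseq(g[[1]], at, at + nchar(hp) - 1L) <- DNAString(hp)
  list(genome = g, start = at, end = at + nchar(hp) - 1L)
}

test_that("precursor extension is clipped and strand-aware", {
  g <- random_test_genome(9, len = 1000L)
  cand <- GRanges("chr1", IRanges(101, 150), strand = "+")
  prec <- build_precursor(cand, g, flank = 50L)
  expect_equal(start(prec$interval), 51L)
  expect_equal(end(prec$interval), 200L)
  expect_equal(nchar(prec$sequence), 150L)
  expect_equal(prec$sequence,
               as.character(subseq(g[[1]], 51, 200)))

  # minus strand: reverse complement of the same interval
  candm <- GRanges("chr1", IRanges(101, 150), strand = "-")
  precm <- build_precursor(candm, g, flank = 50L)
  expect_equal(precm$sequence,
               as.character(reverseComplement(subseq(g[[1]], 51, 200))))

  # candidate near the chromosome start is clipped with a warning
  edge <- GRanges("chr1", IRanges(20, 60), strand = "+")
  expect_warning(pe <- build_precursor(edge, g, flank = 50L),
                 "clipped")
  expect_equal(start(pe$interval), 1L)
})

test_that("mature proposal ranks distinct fragments by abundance", {
  starts <- c(rep(100L, 5L), rep(120L, 3L), rep(140L, 3L),
              rep(c(160L, 180L, 200L, 220L, 240L), each = 2L))
  r <- make_reads("chr1", starts, 21L)
  top <- propose_matures(r)
  expect_length(top, 6L)
  expect_equal(start(top)[1], 100L)
  expect_equal(mcols(top)$count[1], 5L)
  # tie at rank 2 between starts 120 and 140 resolves leftmost-first
  expect_equal(start(top)[2:3], c(120L, 140L))
  # remaining ties (count 2) fill ranks 4-6 leftmost-first
  expect_equal(start(top)[4:6], c(160L, 180L, 200L))
  # a single fragment yields a list of one
  expect_length(propose_matures(make_reads("chr1", 5L, 20L)), 1L)
})

test_that("folding backends are deterministic and sane", {
  f <- fold_rna("GGGGAAAACCCC", backend = "basepair")
  expect_equal(f$structure, "((((....))))")
  expect_lt(f$mfe, 0)
  expect_equal(fold_rna("AAAAAAAA", backend = "basepair")$mfe, 0)
  expect_identical(fold_rna("GGGGAAAACCCC", backend = "basepair"),
                   fold_rna("GGGGAAAACCCC", backend = "basepair"))
  skip_if(Sys.which("RNAfold") == "", "RNAfold unavailable")
  fr <- fold_rna("GGGGAAAACCCC", backend = "rnafold")
  expect_equal(fr$structure, "((((....))))")
  expect_lt(fr$mfe, 0)
})

test_that("empirical MFE p-value hits its extremes and monotonicity", {
  g <- random_test_genome(10, len = 5000L)
  low <- empirical_mfe_pvalue(-1e6, 80L, g, n = 50L, seed = 1,
                              backend = "basepair")
  expect_equal(low$p, 0)
  expect_true(low$significant)
  high <- empirical_mfe_pvalue(1e6, 80L, g, n = 50L, seed = 1,
                               backend = "basepair")
  expect_equal(high$p, 1)
  # monotone: a more negative candidate MFE never raises p (same seed)
  p1 <- empirical_mfe_pvalue(-30, 80L, g, n = 100L, seed = 3,
                             backend = "basepair")$p
  p2 <- empirical_mfe_pvalue(-50, 80L, g, n = 100L, seed = 3,
                             backend = "basepair")$p
  expect_lte(p2, p1)
  expect_error(empirical_mfe_pvalue(-10, 9999L, g, n = 10L),
               "longest chromosome")
})

test_that("duplex geometry classifies canonical and one-sided overhangs", {
  # two-arm stem of 20 pairs with 6-nt loop inside a 60-nt precursor
  db <- paste0(strrep(".", 5), strrep("(", 20), strrep(".", 6),
               strrep(")", 20), strrep(".", 9))
  # mature = the 5' arm; inferred star shifted by 2 gives canonical
  # 2-nt 3' overhangs on both duplex ends
  d <- assess_duplex(db, c(6, 25))
  expect_equal(d$status, "both_3p_2nt")
  expect_equal(d$overhang_mature, 2L)
  expect_equal(d$overhang_star, 2L)
  # star blunt at its own 3' end: overhang only on the mature side
  d2 <- assess_duplex(db, c(6, 25), star = c(34, 51))
  expect_equal(d2$status, "one_side_only")
  # mature entirely in the loop
  d3 <- assess_duplex(db, c(26, 31))
  expect_equal(d3$status, "none")
})

test_that("a planted hairpin is significant and Dicer-compatible", {
  ph <- planted_hairpin_genome()
  cand <- GRanges("chr1", IRanges(ph$start, ph$end), strand = "+")
  reads <- make_reads("chr1", rep(ph$start + 2L, 50L), 21L,
                      seq = as.character(subseq(ph$genome[[1]],
                                                ph$start + 2L,
                                                ph$start + 22L)))
  h <- evaluate_hairpin(cand, reads, ph$genome, n_perm = 300L,
                        seed = 42, backend = "basepair")
  expect_lt(h$empirical_p, 0.05)
  expect_true(h$significant)
  expect_true(h$verdict %in% c("canonical_miRNA", "miRNA_like"))
  # fixed seed: bit-reproducible
  h2 <- evaluate_hairpin(cand, reads, ph$genome, n_perm = 300L,
                         seed = 42, backend = "basepair")
  expect_identical(h[c("structure", "mfe", "empirical_p", "verdict")],
                   h2[c("structure", "mfe", "empirical_p", "verdict")])
})
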