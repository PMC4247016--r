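test_that("read clustering follows the gap rule and read-count floor", {
  # 10 identical reads form one locus
  r <- make_reads("chr1", rep(1001L, 10L), 24L)
  loci <- cluster_srna_loci(r)
  expect_length(loci, 1L)
  expect_equal(mcols(loci)$read_count, 10L)

  # 9 reads stay below the minimum support
  expect_length(cluster_srna_loci(make_reads("chr1", rep(1001L, 9L),
                                             24L)), 0L)

  # two pile groups separated by a gap of 130 >= 100 form two loci
  r2 <- make_reads("chr1", c(rep(1L, 10L), rep(151L, 10L)), 20L)
  loci2 <- cluster_srna_loci(r2, max_gap = 100L, min_reads = 10L)
  expect_length(loci2, 2L)
  # a gap of exactly 99 links them
  r3 <- make_reads("chr1", c(rep(1L, 10L), rep(120L, 10L)), 20L)
  expect_length(cluster_srna_loci(r3), 1L)
})

test_that("clustering equals brute-force single linkage on random sets", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(2:50, 1L)
    st <- sample.int(3000L, n, replace = TRUE)
    wd <- sample(18:30, n, replace = TRUE)
    r <- make_reads("chr1", st, wd)
    comp <- brute_single_linkage(start(r), end(r), 100L)
    loci <- cluster_srna_loci(r, min_reads = 1L, classify = FALSE)
    # same number of clusters
    expect_equal(length(loci), length(unique(comp)))
    # identical partition: each oracle component maps into exactly one
    # locus, and no locus mixes components
    hits <- findOverlaps(r, loci, ignore.strand = TRUE)
    locus_of <- integer(n)
    locus_of[queryHits(hits)] <- subjectHits(hits)
    expect_true(all(tapply(locus_of, comp,
                           function(v) length(unique(v))) == 1L))
    expect_equal(length(unique(locus_of)), length(unique(comp)))
    # partition property: every read in exactly one locus
    expect_equal(sum(mcols(loci)$read_count), n)
  }
})

test_that("distribution classes separate piles from spread coverage", {
  # 100 identical plus-strand reads: maximal strandedness/localization
  pile <- cluster_srna_loci(make_reads("chr1", rep(501L, 100L), 24L))
  expect_equal(mcols(pile)$distribution_class, "PILE")
  expect_equal(mcols(pile)$strand_fraction, 1)
  expect_equal(mcols(pile)$localization, 1)

  # both strands, scattered 5' ends over 2 kb
  set.seed(3)
  spread <- make_reads("chr1", sample(1000:3000, 100L, TRUE), 26L,
                       strand = sample(c("+", "-"), 100L, TRUE))
  sl <- cluster_srna_loci(spread)
  expect_true(all(mcols(sl)$distribution_class == "DISTRIBUTED"))

  # dominant length ties break toward the shorter length
  r <- make_reads("chr1", rep(801L, 10L), rep(c(24L, 25L), each = 5L))
  expect_equal(mcols(cluster_srna_loci(r))$dominant_length, 24)
})

test_that("candidate filters enforce length, complexity and typing", {
  set.seed(5)
  genome <- random_test_genome(5, len = 5000L)
  # entropy-rich intergenic pile of 24-nt reads is retained
  ann <- load_annotations(genome = genome,
                          trnas = make_trna_model("chr1", 3000L))
  pile <- cluster_srna_loci(make_reads("chr1", rep(1001L, 50L), 24L))
  out <- filter_candidates(pile, ann)
  expect_true(mcols(out)$pass_all)
  expect_equal(mcols(out)$candidate_type, "intergenic-novel")

  # dominant length 31 fails the 19-29 nt window
  long <- cluster_srna_loci(make_reads("chr1", rep(1001L, 50L), 31L))
  expect_false(mcols(filter_candidates(long, ann))$pass_all)
  expect_false(mcols(filter_candidates(long, ann))$pass_length)

  # a pile on a homopolymer-like stretch fails the complexity filter
  poly <- genome
  Biostrings::subseq(poly[["chr1"]], 2001L, 2030L) <-
    Biostrings::DNAString(strrep("A", 30L))
  ann_poly <- load_annotations(genome = poly)
  low <- cluster_srna_loci(make_reads("chr1", rep(2001L, 50L), 24L))
  expect_false(mcols(filter_candidates(low, ann_poly))$pass_complexity)

  # tRNA overlap takes precedence in candidate typing
  tr <- cluster_srna_loci(make_reads("chr1", rep(3050L, 20L), 19L))
  expect_equal(mcols(filter_candidates(tr, ann))$candidate_type,
               "tRNA-associated")

  expect_error(filter_candidates(pile, load_annotations()),
               "genome")
})

test_that("library merging unions intervals and counts support", {
  a <- GRanges("chr1", IRanges(100, 149))
  b <- GRanges("chr1", IRanges(140, 199))
  m <- merge_across_libraries(list(NL = a, HL = b))
  expect_length(m, 1L)
  expect_equal(start(m), 100L)
  expect_equal(end(m), 199L)
  expect_equal(mcols(m)$support, 2L)

  disjoint <- merge_across_libraries(
    list(NL = GRanges("chr1", IRanges(1, 50)),
         HL = GRanges("chr1", IRanges(500, 550))))
  expect_length(disjoint, 2L)
  expect_equal(mcols(disjoint)$support, c(1L, 1L))

  # idempotent and order-independent
  sets <- list(NL = a, HL = b, LL = GRanges("chr2", IRanges(7, 30)))
  key <- function(gr) sort(paste(seqnames(gr), start(gr), end(gr)))
  m1 <- merge_across_libraries(sets)
  m2 <- merge_across_libraries(rev(sets))
  expect_equal(key(m1), key(m2))
  again <- merge_across_libraries(list(merged = granges(m1)))
  expect_equal(key(again), key(m1))
})
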