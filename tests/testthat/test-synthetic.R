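test_that("bundles are deterministic under a fixed seed", {
  b1 <- synth_generate(synth_config(seed = 13))
  b2 <- synth_generate(synth_config(seed = 13))
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(as.data.frame(b1$reads), as.data.frame(b2$reads))
  expect_identical(b1$truth, b2$truth)
  # written bundles are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  synth_write_bundle(b1, d1)
  synth_write_bundle(b2, d2)
  f1 <- list.files(d1)
  expect_identical(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  b3 <- synth_generate(synth_config(seed = 14))
  expect_false(identical(as.character(b1$genome),
                         as.character(b3$genome)))
})

test_that("planted features match their configuration", {
  cfg <- synth_config(seed = 17)
  b <- synth_generate(cfg)
  tl <- b$truth$loci
  expect_equal(sum(tl$type == "pile"), cfg$pile$n)
  expect_equal(sum(tl$type == "trna"), cfg$trna$n)
  expect_equal(sum(tl$type == "te"), length(cfg$te$lengths))
  expect_equal(sum(tl$type == "hmr"), cfg$hmr$n)
  # a pile of depth d produces d read records at one position
  p1 <- tl[tl$feature == "pile1", ]
  in_p1 <- b$reads[overlapsAny(b$reads,
                               GRanges(p1$chrom,
                                       IRanges(p1$start, p1$end)))]
  expect_gte(length(in_p1), cfg$pile$depth)
  # genome-templated CCA at every tRNA 3' terminus
  trnas <- b$annotations$trnas
  for (i in seq_along(trnas)) {
    gene <- b$genome[[as.character(seqnames(trnas))[i]]]
    s <- Biostrings::subseq(gene, start(trnas)[i], end(trnas)[i])
    if (as.character(strand(trnas))[i] == "-") {
      s <- reverseComplement(s)
    }
    expect_equal(as.character(Biostrings::subseq(s, 70, 72)), "CCA")
  }
  # U2-like locus: two populations, deep 3' and shallow 5'
  u2 <- tl[tl$feature == "u2", ]
  u2_reads <- b$reads[overlapsAny(
    b$reads, GRanges(u2$chrom, IRanges(u2$start, u2$end)))]
  tab <- sort(table(start(u2_reads)), decreasing = TRUE)
  expect_equal(unname(tab[1]), cfg$u2$depth3)
  expect_equal(unname(tab[2]), cfg$u2$depth5)
})

test_that("HMR pile spacing follows the configured period", {
  cov <- synth_hmr_coverage(period = 180, span = 5000, seed = 3)
  expect_length(cov, 10000L)
  # pile centers = midpoints of above-threshold runs (piles are ~30x
  # deep on a ~0.2x background)
  r <- rle(cov > 10)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  centers <- (starts[r$values] + ends[r$values]) / 2
  expect_gt(length(centers), 20L)
  spacing <- diff(centers)
  spacing <- spacing[spacing > 100]  # ignore split piles
  expect_lt(abs(median(spacing) - 180), 20)
})

test_that("multimappers are duplicated across TE copies with weight 1/2", {
  b <- synth_generate(synth_config(seed = 19))
  multi <- b$reads[mcols(b$reads)$multiplicity == 2L]
  expect_gt(length(multi), 0L)
  expect_equal(unique(mcols(multi)$weight), 0.5)
  # multimappers lie in the first two TE regions
  te12 <- b$annotations$repeats[1:2]
  expect_true(all(overlapsAny(multi, te12, ignore.strand = TRUE)))
})

test_that("recovery reports summarize detection against truth", {
  b <- synth_generate(synth_config(seed = 23))
  loci <- cluster_srna_loci(b$reads)
  cmp <- truth_compare(loci = loci, truth_loci = b$truth$loci,
                       class_filter = "PILE")
  expect_gte(cmp$loci$recall, 0.95)
  expect_gte(cmp$loci$precision, 0.95)
  # periodic recovery within one Fourier bin
  cov <- compute_coverage(b$reads, mode = "reweighted",
                          seqlengths = setNames(width(b$genome),
                                                names(b$genome)))
  w <- scan_periodicity(cov)
  reg <- call_periodic_regions(w)
  pc <- truth_compare(periodic = reg,
                      truth_periodic = b$truth$periodic)
  expect_equal(pc$periodic$recall, 1)
  expect_true(all(pc$periodic$period_error <=
                    180^2 / 1000, na.rm = TRUE))
})
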