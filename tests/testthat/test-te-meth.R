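test_that("RPKM matches its closed form and scale invariance", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(20, 1000, 2e6), rpkm(10, 1000, 1e6))
  expect_error(rpkm(1, 0, 1e6), "zero-length")
  expect_error(rpkm(1, 100, 0), "total_aligned")

  region <- GRanges("chr1", IRanges(1, 1000))
  reads <- make_reads("chr1", seq(10, 910, by = 100), 20L)
  expect_equal(srna_rpkm(region, reads, total_aligned = 1e6), 10)
  # reweighting: multiplicity-2 reads contribute half a count
  reads2 <- make_reads("chr1", seq(10, 910, by = 100), 20L, mult = 2L)
  expect_equal(srna_rpkm(region, reads2, total_aligned = 1e6), 5)
})

test_that("methylation level is the methylated-probe proportion", {
  probes <- GRanges("chr1", IRanges(c(10, 60, 110, 500), width = 2),
                    call = c(1L, 1L, 0L, 1L))
  regions <- GRanges("chr1", IRanges(c(1, 50, 2000), c(120, 70, 2100)))
  ml <- methylation_level(regions, probes)
  expect_equal(ml$level[1], 2 / 3)
  # nested region inherits only its own overlapping probes
  expect_equal(ml$n_probes[2], 1L)
  expect_equal(ml$level[2], 1)
  # no probes: undefined, not zero
  expect_true(is.na(ml$level[3]))
})

test_that("RPKM bins and expression classes use the stated cutoffs", {
  expect_equal(as.character(bin_rpkm(c(4.9, 7, 10.5, 5, 10))),
               c("low", "middle", "high", "middle", "middle"))

  expr <- 1:100
  cls <- expression_class(expr)
  # the 15th percentile splits ranks 1-15 from the rest (type-7
  # quantile of 1..100 at 0.15 is 15.85)
  expect_equal(sum(cls == "low"), 15L)
  expect_equal(as.character(cls[16]), "expressed")
  # sort-based oracle for the threshold
  thr <- sort(expr)[ceiling(0.15 * length(expr))]
  expect_true(all(expr[cls == "low"] <= thr + 1))
  # all-equal expressions collapse to one class
  expect_true(all(expression_class(rep(3, 10)) == "low"))
})

test_that("Mann-Whitney agrees with exact enumeration on small groups", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(3:5, 1L)
    m <- sample(3:5, 1L)
    vals <- sample.int(1000L, n + m)  # tie-free
    x <- vals[seq_len(n)]
    y <- vals[-seq_len(n)]
    p_pkg <- association_tests(c(x, y),
                               factor(rep(c("low", "expressed"),
                                          c(n, m)),
                                      levels = c("low", "expressed"))
                               )$mann_whitney$p.value
    expect_equal(p_pkg, brute_mw_greater(x, y), tolerance = 1e-12)
  }
  # direction: a clearly higher first group is significant one-sided
  res <- association_tests(c(10, 11, 12, 1, 2, 3),
                           factor(rep(c("low", "expressed"), each = 3),
                                  levels = c("low", "expressed")))
  expect_equal(res$mann_whitney$p.value, 1 / 20)
  # and the reverse direction is not
  res2 <- association_tests(c(1, 2, 3, 10, 11, 12),
                            factor(rep(c("low", "expressed"), each = 3),
                                   levels = c("low", "expressed")))
  expect_equal(res2$mann_whitney$p.value, 1)
  # too-small groups warn and return NA
  expect_warning(
    res3 <- association_tests(c(1, 5, 6, 7),
                              factor(c("low", rep("expressed", 3)),
                                     levels = c("low", "expressed"))),
    "too small")
  expect_true(is.na(res3$mann_whitney$p.value))
})

test_that("correlations match closed forms on monotone/linear data", {
  x <- c(1, 2, 3, 4, 5)
  res <- association_tests(exp(x), methylation = x)
  expect_equal(res$spearman, 1)
  res2 <- association_tests(2 * x + 1, methylation = x)
  expect_equal(res2$pearson, 1)
  # identical values: undefined, reported NA
  res3 <- association_tests(rep(1, 5), methylation = x)
  expect_true(is.na(res3$spearman))
  # inter-library correlation matrix
  m <- cbind(NL = x, HL = x + rnorm(5, 0, 1e-6))
  res4 <- association_tests(x, library_matrix = m)
  expect_equal(res4$library_correlation["NL", "HL"], 1)
})

test_that("5' composition recovers the configured U bias", {
  mat <- five_prime_composition(c("UAA", "UCC", "GAA"), n_pos = 3)
  expect_equal(mat["U", 1], 2 / 3)
  expect_equal(colSums(mat), setNames(rep(1, 3), colnames(mat)))

  b <- synth_generate(synth_config(seed = 4))
  te_reads <- b$reads[overlapsAny(b$reads, b$annotations$repeats,
                                  ignore.strand = TRUE)]
  u1 <- five_prime_composition(te_reads)["U", 1]
  n <- length(te_reads)
  ci <- qnorm(0.995) * sqrt(0.6 * 0.4 / n)
  expect_lt(abs(u1 - 0.6), ci + 0.01)
})

test_that("synthetic TEs show the methylation/expression association", {
  b <- synth_generate(synth_config(seed = 6))
  te <- b$annotations$repeats
  ex <- b$expression[b$expression$type == "TE", ]
  stats <- te_region_stats(te, b$reads, probes = b$annotations$methylation,
                           expression = ex$expression)
  tests <- association_tests(stats$srna_rpkm,
                             expr_class = stats$expression_class,
                             methylation = stats$methylation_level)
  expect_lt(tests$mann_whitney$p.value, 0.05)
  expect_gt(tests$spearman, 0)
})
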