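test_that("window FFT magnitudes match the brute-force DFT", {
  set.seed(31)
  for (n in c(64L, 256L, 1000L, 1024L)) {
    x <- rpois(n, 2)
    w <- window_fft(x)
    expect_equal(w$magnitudes, brute_dft_mags(x - mean(x)),
                 tolerance = 1e-6)
  }
})

test_that("closed-form spectra give exact main periods", {
  # pure cosine of period 200 concentrates in one bin
  x <- cos(2 * pi * (0:999) / 200)
  w <- window_fft(x, refine = FALSE)
  expect_equal(w$main_period, 200)
  expect_equal(w$coefficient, 1, tolerance = 1e-9)
  # refinement stays within a fraction of a bin
  expect_lt(abs(window_fft(x)$main_period - 200), 2)

  # impulse train with 100-nt spacing
  imp <- numeric(1000)
  imp[seq(1, 1000, by = 100)] <- 5
  wi <- window_fft(imp, refine = FALSE)
  expect_equal(wi$main_period, 100)
  expect_true(wi$harmonic)  # equal-magnitude harmonic at 50 nt
  expect_lt(abs(window_fft(imp)$main_period - 100), 1)

  # degenerate windows
  expect_equal(window_fft(numeric(1000))$coefficient, 0)
  expect_true(is.na(window_fft(numeric(1000))$main_period))
  expect_equal(window_fft(rep(7, 1000))$coefficient, 0)
})

test_that("magnitudes are invariant under circular shifts", {
  set.seed(32)
  x <- synth_hmr_coverage(seed = 32)[1:1000]
  for (off in c(13L, 250L, 999L)) {
    xs <- c(x[(off + 1):1000], x[1:off])
    expect_equal(window_fft(xs)$magnitudes, window_fft(x)$magnitudes,
                 tolerance = 1e-9)
  }
})

test_that("scan flags significant windows only where coverage is periodic", {
  cov <- synth_hmr_coverage(period = 180, span = 5000, flank = 2500,
                            seed = 41)
  w <- scan_periodicity(cov)
  expect_true(sum(w$significant) >= 3L)
  sig <- w[w$significant, ]
  # significant windows concentrate on the planted span
  expect_true(all(sig$end > 2300 & sig$start < 7800))
  expect_lt(abs(modal_main_period(w) - 180), 5)
  # empty track yields an empty window list
  empty <- scan_periodicity(numeric(500), window = 1000L)
  expect_equal(nrow(empty), 0L)
})

test_that("periodic regions require three significant windows in a span", {
  win <- data.frame(chrom = "chr1",
                    start = c(1, 101, 201, 9001),
                    end = c(1000, 1100, 1200, 10000),
                    main_period = c(180, 180, 90, 500),
                    coefficient = 0.9, harmonic = FALSE,
                    significant = c(TRUE, TRUE, TRUE, FALSE))
  reg <- call_periodic_regions(win)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_significant_windows, 3L)
  # members {180, 180, 90} average to 150, outside the 175-225 band
  expect_equal(reg$mean_period, 150)
  expect_false(reg$in_band)

  # two significant windows are not enough
  win2 <- win[1:2, ]
  expect_equal(nrow(call_periodic_regions(win2)), 0L)

  # windows further apart than the span do not group
  win3 <- win
  win3$start <- c(1, 6001, 12001, 2e5)
  win3$end <- win3$start + 999
  win3$significant <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(nrow(call_periodic_regions(win3)), 0L)
})

test_that("overlap report covers both periodic regions and HMRs", {
  reg <- data.frame(chrom = "chr1", start = c(1000, 9000),
                    end = c(2000, 9500))
  hmr <- GRanges("chr1", IRanges(c(500, 30000), c(2500, 31000)))
  loci <- GRanges("chr1", IRanges(c(400, 30100), c(2200, 30900)))
  rep_ <- hmr_overlap(reg, hmr, loci = loci)
  expect_equal(rep_$frac_regions_overlapping, 0.5)
  expect_equal(rep_$frac_hmr_with_locus, 1)
  # HMR 1 covered (2200-500+1)/2001 = 0.85 > 0.75; HMR 2 covered 0.8
  expect_equal(rep_$frac_hmr_covered, 1)
  # disjoint sets report zero overlap
  none <- hmr_overlap(reg, GRanges("chr2", IRanges(1, 10)))
  expect_equal(none$frac_regions_overlapping, 0)
})
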