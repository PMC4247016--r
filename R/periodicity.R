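#' Main period of a coverage window by discrete Fourier transform
#'
#' Computes the DFT magnitude spectrum of a coverage window (mean
#' removed, DC excluded), restricts the search to an allowed period
#' band, and extracts the main period and its normalized coefficient.
#'
#' The main frequency bin `k*` maximizes the magnitude within the band
#' (ties broken toward the smaller `k`, i.e. the longer period). The
#' coefficient is the magnitude at `k*` divided by the sum of non-DC
#' magnitudes over the half spectrum, a scale-free value in `[0, 1]`
#' that equals 1 for a pure sinusoid. When the magnitudes at `k*` and
#' at its half- or double-frequency harmonic agree within 5%, the
#' longer period is reported and the call is flagged as harmonic.
#'
#' The integer-bin period `window/k*` is optionally refined by scanning
#' the discrete-time Fourier transform on a fine frequency grid around
#' `k*`, which resolves periods that fall between Fourier bins (e.g. a
#' 180 nt spacing in a 1000 nt window).
#'
#' @param values Numeric coverage vector (one window).
#' @param min_period,max_period Allowed period band in nt (defaults 50
#'   and 500); bins adjacent to DC otherwise dominate.
#' @param detrend Subtract the window mean before transforming
#'   (default `TRUE`).
#' @param refine Refine the period by a fine DTFT grid search around
#'   the main bin (default `TRUE`).
#' @return List: `main_period` (nt, `NA` for an empty window),
#'   `coefficient`, `k` (main bin), `harmonic` (logical),
#'   `magnitudes` (half-spectrum DFT magnitudes, `k = 1..n/2`).
#' @export
window_fft <- function(values, min_period = 50, max_period = 500,
                       detrend = TRUE, refine = TRUE) {
  n <- length(values)
  stopifnot(n >= 4L)
  x <- as.numeric(values)
  if (all(x == 0)) {
    return(list(main_period = NA_real_, coefficient = 0, k = NA_integer_,
                harmonic = FALSE,
                magnitudes = rep(0, floor(n / 2))))
  }
  if (detrend) x <- x - mean(x)
  sp <- fft(x)
  nk <- floor(n / 2)
  mags <- Mod(sp)[2:(nk + 1L)]  # k = 1 .. n/2, DC excluded
  kmin <- max(1L, ceiling(n / max_period))
  kmax <- min(nk, floor(n / min_period))
  if (kmin > kmax) stop_ctx("period band [%g, %g] empty for window of %d nt",
                            min_period, max_period, n)
  band <- kmin:kmax
  total <- sum(mags)
  tol <- 0.05
  if (!refine) {
    # plain Fourier-bin extraction: argmax over the band, ties and
    # near-ties (within 5%) resolved toward the smaller k (longer
    # period, the fundamental of a harmonic pair)
    mb <- mags[band]
    k <- band[min(which(mb >= (1 - tol) * max(mb)))]
    harmonic <- 2L * k <= nk && mags[2L * k] >= (1 - tol) * mags[k]
    coeff <- if (total > 0) mags[k] / total else 0
    return(list(main_period = n / k, coefficient = coeff, k = k,
                harmonic = harmonic, magnitudes = mags))
  }
  # a period falling between Fourier bins loses peak magnitude to
  # leakage, which can make an on-bin harmonic look dominant; compare
  # candidate peaks by their refined DTFT maxima instead of bin values
  mb <- mags[band]
  is_peak <- vapply(seq_along(band), function(i) {
    (i == 1L || mb[i] >= mb[i - 1L]) &&
      (i == length(band) || mb[i] >= mb[i + 1L])
  }, logical(1))
  cand <- band[is_peak]
  cand <- cand[order(-mags[cand])]
  cand <- head(cand, 5L)
  # zero-padded FFT evaluates the DTFT on a 1/pad-bin grid in one
  # O(N log N) pass; parabolic interpolation around each padded peak
  # gives sub-grid frequency precision
  pad <- 16L
  mpad <- Mod(fft(c(x, numeric((pad - 1L) * n))))
  ref <- lapply(cand, function(k) {
    refine_peak_padded(mpad, pad, max(kmin, k - 1), min(kmax, k + 1))
  })
  fs <- vapply(ref, `[[`, numeric(1), "f")
  ms <- vapply(ref, `[[`, numeric(1), "mag")
  # best refined peak; a sub-harmonic (frequency ratio >= 1.7) within
  # 5% of the best magnitude wins as the fundamental (longer period)
  sel <- which.max(ms)
  sub <- which(ms >= (1 - tol) * ms[sel] & fs <= fs[sel] / 1.7)
  if (length(sub) > 0L) sel <- sub[which.min(fs[sub])]
  f <- fs[sel]
  m <- ms[sel]
  harmonic <- any(abs(fs - 2 * f) < 0.5 & ms >= (1 - tol) * m)
  k <- cand[sel]
  coeff <- if (total > 0) min(1, m / total) else 0
  list(main_period = n / f, coefficient = coeff, k = k,
       harmonic = harmonic, magnitudes = mags)
}

# Argmax of the zero-padded magnitude spectrum within the frequency
# interval [f_lo, f_hi] (cycles per unpadded window), refined by
# parabolic interpolation of the three bins around the peak.
refine_peak_padded <- function(mpad, pad, f_lo, f_hi) {
  npad <- length(mpad)
  # padded bin j (1-based) holds frequency (j - 1) / pad
  j_lo <- max(2L, floor(f_lo * pad) + 1L)
  j_hi <- min(npad %/% 2L, ceiling(f_hi * pad) + 1L)
  jj <- j_lo:j_hi
  j0 <- jj[which.max(mpad[jj])]
  f <- (j0 - 1) / pad
  m <- mpad[j0]
  if (j0 > 2L && j0 < npad %/% 2L) {
    a <- mpad[j0 - 1L]; b <- mpad[j0]; c <- mpad[j0 + 1L]
    # interpolate only at a strict local maximum, which bounds the
    # shift to half a padded bin and the magnitude to ~b
    if (a < b && c < b) {
      delta <- 0.5 * (a - c) / (a - 2 * b + c)
      f <- f + delta / pad
      m <- b - 0.25 * (a - c) * delta
    }
  }
  f <- min(max(f, f_lo), f_hi)
  list(f = f, mag = m)
}

#' Sliding-window periodicity scan of a coverage track
#'
#' Slides a window (default 1000 bp, 100 bp increments) along each
#' chromosome's coverage, computes the main period and normalized FFT
#' coefficient per window, and flags windows whose coefficient exceeds
#' `sig_frac` (default 75%) of the maximal coefficient over the whole
#' scanned set as carrying a significant period.
#'
#' Multimapping reads are included via the reweighted coverage mode;
#' build the track with `compute_coverage(..., mode = "reweighted")`.
#'
#' @param track Coverage: a numeric vector, an `Rle`, or an `RleList`
#'   (per chromosome, as from [compute_coverage()]).
#' @param window Window length in nt (default 1000).
#' @param step Increment in nt (default 100).
#' @param sig_frac Significance threshold as a fraction of the maximal
#'   coefficient (default 0.75), applied globally across the scan.
#' @param ... Passed to [window_fft()].
#' @return Data frame of windows: `chrom`, `start` (1-based), `end`,
#'   `main_period`, `coefficient`, `harmonic`, `significant`.
#' @export
scan_periodicity <- function(track, window = 1000L, step = 100L,
                             sig_frac = 0.75, ...) {
  if (is.numeric(track)) track <- list(chr = track)
  if (methods::is(track, "Rle")) track <- list(chr = track)
  res <- lapply(names(track), function(chrom) {
    v <- as.numeric(track[[chrom]])
    n <- length(v)
    if (n < window) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), main_period = numeric(0),
                        coefficient = numeric(0), harmonic = logical(0)))
    }
    starts <- seq.int(1L, n - window + 1L, by = step)
    rows <- lapply(starts, function(s) {
      w <- window_fft(v[s:(s + window - 1L)], ...)
      data.frame(chrom = chrom, start = s, end = s + window - 1L,
                 main_period = w$main_period,
                 coefficient = w$coefficient, harmonic = w$harmonic)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), main_period = numeric(0),
                      coefficient = numeric(0), harmonic = logical(0),
                      significant = logical(0)))
  }
  maxc <- max(out$coefficient)
  out$significant <- !is.na(out$main_period) &
    out$coefficient > sig_frac * maxc
  out
}

#' Call periodic regions from scanned windows
#'
#' Merges significant windows into periodic-region calls: any run of at
#' least `min_significant` significant windows falling within a `span`
#' bp stretch contributes; overlapping qualifying windows are unioned
#' into maximal regions. Each region reports its window count, mean
#' main period, and whether the mean lies in the reference period band
#' (default 175-225 nt).
#'
#' @param windows Data frame from [scan_periodicity()].
#' @param span Span in bp within which significant windows are grouped
#'   (default 5000).
#' @param min_significant Minimum significant windows per group
#'   (default 3).
#' @param band Reference period band in nt (default `c(175, 225)`).
#' @return Data frame of regions: `chrom`, `start`, `end`,
#'   `n_significant_windows`, `mean_period`, `in_band`.
#' @export
call_periodic_regions <- function(windows, span = 5000L,
                                  min_significant = 3L,
                                  band = c(175, 225)) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0),
                      n_significant_windows = integer(0),
                      mean_period = numeric(0), in_band = logical(0))
  sig <- windows[windows$significant, , drop = FALSE]
  if (nrow(sig) < min_significant) return(empty)
  out <- lapply(split(sig, sig$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    k <- nrow(s)
    if (k < min_significant) return(NULL)
    # every run of min_significant consecutive significant windows
    # fitting in a span contributes its whole span; overlapping spans
    # merge into maximal regions
    spans <- NULL
    for (i in seq_len(k - min_significant + 1L)) {
      j <- i + min_significant - 1L
      if (s$end[j] - s$start[i] + 1L <= span) {
        spans <- rbind(spans, c(s$start[i], s$end[j]))
      }
    }
    if (is.null(spans)) return(NULL)
    gr <- reduce(IRanges(spans[, 1], spans[, 2]))
    s <- s[overlapsAny(IRanges(s$start, s$end), gr), , drop = FALSE]
    members <- findOverlaps(IRanges(s$start, s$end), gr)
    mp <- vapply(seq_along(gr), function(g) {
      mean(s$main_period[queryHits(members)[subjectHits(members) == g]])
    }, numeric(1))
    nw <- vapply(seq_along(gr), function(g) {
      sum(subjectHits(members) == g)
    }, integer(1))
    data.frame(chrom = s$chrom[1L], start = start(gr), end = end(gr),
               n_significant_windows = nw, mean_period = mp,
               in_band = mp >= band[1] & mp <= band[2])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Overlap of periodic regions and loci with highly methylated regions
#'
#' Reports (i) the fraction of periodic regions overlapping any highly
#' methylated region (HMR) and (ii) the fraction of HMRs overlapped by
#' sRNA-producing loci, including the stricter criterion of being
#' covered on more than `frac_len` (default 75%) of their length.
#'
#' @param regions Periodic regions: data frame from
#'   [call_periodic_regions()] or a `GRanges`.
#' @param hmr `GRanges` of highly methylated regions.
#' @param loci Optional `GRanges` of sRNA-producing loci for the HMR
#'   side of the report.
#' @param frac_len Length-coverage threshold (default 0.75).
#' @return List: `n_regions`, `n_regions_overlapping`,
#'   `frac_regions_overlapping`, and (with `loci`) `n_hmr`,
#'   `frac_hmr_with_locus`, `frac_hmr_covered`.
#' @export
hmr_overlap <- function(regions, hmr, loci = NULL, frac_len = 0.75) {
  if (is.data.frame(regions)) {
    regions <- if (nrow(regions) == 0L) GRanges() else
      GRanges(regions$chrom, IRanges(regions$start, regions$end))
  }
  res <- list(n_regions = length(regions))
  ov <- suppressWarnings(overlapsAny(regions, hmr,
                                     ignore.strand = TRUE))
  res$n_regions_overlapping <- sum(ov)
  res$frac_regions_overlapping <-
    if (length(regions) > 0L) mean(ov) else NA_real_
  if (!is.null(loci)) {
    res$n_hmr <- length(hmr)
    res$frac_hmr_with_locus <-
      mean(suppressWarnings(overlapsAny(hmr, loci,
                                        ignore.strand = TRUE)))
    cov_frac <- vapply(seq_along(hmr), function(i) {
      hit <- IRanges::intersect(ranges(hmr[i]),
                                ranges(reduce(loci[seqnames(loci) ==
                                  as.character(seqnames(hmr))[i]],
                                  ignore.strand = TRUE)))
      sum(width(hit)) / width(hmr)[i]
    }, numeric(1))
    res$frac_hmr_covered <- mean(cov_frac > frac_len)
  }
  res
}

#' Modal main period of significant windows
#'
#' The mode of the (nearest-nt rounded) main periods over significant
#' windows of a scan; ties break toward the shorter period value.
#'
#' @param windows Data frame from [scan_periodicity()].
#' @return Numeric modal period in nt (`NA` if no significant window).
#' @export
modal_main_period <- function(windows) {
  p <- windows$main_period[windows$significant]
  p <- p[!is.na(p)]
  if (length(p) == 0L) return(NA_real_)
  modal_value(round(p))
}
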