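#' Frequency band schemes
#'
#' The canonical five resting-EEG bands over the 2-46 Hz analysis range.
#' The conventional printed integer limits (delta 2-3, theta 4-8, alpha 9-13,
#' beta 14-30, gamma 31-45 Hz) leave 1-Hz gaps between bands; the default
#' scheme therefore uses the contiguous half-open partition [2,4), [4,9),
#' [9,14), [14,31), [31,46), so that relative band powers sum to one.  The
#' `"printed"` variant keeps the integer limits (each band [lo, hi+1) is
#' replaced by [lo, hi]) for strict replication of tabulated conventions.
#'
#' @param scheme `"partition"` (default) or `"printed"`, or a data.frame with
#'   columns `name`, `f_lo`, `f_hi` for a custom scheme.
#' @return A `band_scheme` object: data.frame with `name`, `f_lo`, `f_hi`.
#' @export
band_scheme <- function(scheme = "partition") {
  if (is.data.frame(scheme)) {
    b <- scheme
    stopifnot(all(c("name", "f_lo", "f_hi") %in% names(b)))
  } else if (identical(scheme, "partition")) {
    b <- data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
                    f_lo = c(2, 4, 9, 14, 31),
                    f_hi = c(4, 9, 14, 31, 46))
  } else if (identical(scheme, "printed")) {
    b <- data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
                    f_lo = c(2, 4, 9, 14, 31),
                    f_hi = c(3, 8, 13, 30, 45))
  } else stop("unknown band scheme: ", scheme)
  if (any(b$f_hi <= b$f_lo)) stop("band intervals must have f_hi > f_lo")
  if (is.unsorted(b$f_lo, strictly = TRUE) ||
      any(utils::head(b$f_hi, -1) > utils::tail(b$f_lo, -1) + 1e-9))
    stop("bands must be non-overlapping and strictly increasing")
  if (min(b$f_lo) < 2 - 1e-9 || max(b$f_hi) > 46 + 1e-9)
    stop("bands must lie within the 2-46 Hz analysis range")
  structure(b, class = c("band_scheme", "data.frame"))
}

#' Welch power spectral density
#'
#' Welch's averaged-periodogram PSD per channel.  Retained epochs are
#' concatenated and cut into `window_len_s`-second segments with the given
#' overlap; each segment is demeaned, tapered, and its one-sided periodogram
#' accumulated.  The density normalization satisfies Parseval: the integral
#' of the PSD over frequency equals the signal variance up to windowing bias.
#'
#' @param rec An `eeg_recording` (continuous or epoched; epochs are
#'   concatenated in order).
#' @param window_len_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @param window Taper: `"hamming"`, `"hann"` or `"rectangular"`.
#' @return A `power_spectrum`: list with `freqs` (Hz), `psd` (channel x
#'   frequency, uV^2/Hz), and method metadata.
#' @export
welch_psd <- function(rec, window_len_s = 2.0, overlap = 0.5,
                      window = "hamming") {
  stopifnot(inherits(rec, "eeg_recording"), overlap >= 0, overlap < 1)
  x <- flatten_epochs(rec)
  fs <- rec$fs
  nper <- round(window_len_s * fs)
  if (nper > ncol(x))
    stop("Welch window (", nper, " samples) longer than data (",
         ncol(x), " samples)")
  k <- seq(0, nper - 1)
  w <- switch(window,
              hamming = 0.54 - 0.46 * cos(2 * pi * k / (nper - 1)),
              hann = 0.5 - 0.5 * cos(2 * pi * k / (nper - 1)),
              rectangular = rep(1, nper),
              stop("unknown window: ", window))
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, ncol(x) - nper + 1, by = step)
  scale <- 1 / (fs * sum(w^2))
  half <- nper %/% 2 + 1
  nch <- nrow(x)
  # all (segment x channel) windows in one matrix FFT
  idx <- outer(seq_len(nper) - 1L, starts, `+`)          # nper x nseg
  segs <- matrix(t(x)[as.vector(idx), ], nper)           # nper x (nseg*nch)
  segs <- segs - rep(colMeans(segs), each = nper)
  ncols <- ncol(segs)
  p2 <- matrix(0, half, ncols)
  for (j0 in seq(1, ncols, by = 4096)) {                 # cap FFT memory
    jj <- j0:min(j0 + 4095, ncols)
    p2[, jj] <- Mod(stats::mvfft(segs[, jj, drop = FALSE] *
                                   w)[seq_len(half), , drop = FALSE])^2
  }
  acc <- apply(array(p2, c(half, length(starts), nch)), c(1, 3), sum)
  psd <- t(acc) * scale / length(starts)
  # one-sided doubling (all bins except DC and, for even nper, Nyquist)
  dbl <- rep(2, half); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[half] <- 1
  psd <- psd * rep(dbl, each = nrow(psd))
  structure(list(freqs = seq(0, by = fs / nper, length.out = half),
                 psd = psd, labels = rec$labels, fs = fs,
                 window_len_s = window_len_s, overlap = overlap,
                 window = window, n_segments = length(starts)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d ch, %d bins (0-%g Hz), %d Welch segments\n",
              nrow(x$psd), length(x$freqs), max(x$freqs), x$n_segments))
  invisible(x)
}

#' Relative band power
#'
#' Fraction of total spectral power per channel falling in each band:
#' `RP(ch, band) = sum(psd[ch, f in band]) / sum(psd[ch, f in total_range])`,
#' with half-open bins `f_lo <= f < f_hi`.  The aperiodic (1/f) component is
#' part of the totals by design; no aperiodic removal is performed.
#'
#' @param ps A `power_spectrum`.
#' @param scheme A `band_scheme` (default: the five-band partition).
#' @param total_range Denominator frequency range, default `c(2, 46)` Hz,
#'   half-open.
#' @return A `band_power` object: channel x band matrix of fractions, with
#'   the scheme attached as attribute `"scheme"`.
#' @export
relative_band_power <- function(ps, scheme = band_scheme(),
                                total_range = c(2, 46)) {
  stopifnot(inherits(ps, "power_spectrum"))
  f <- ps$freqs
  tot_idx <- f >= total_range[1] & f < total_range[2]
  total <- rowSums(ps$psd[, tot_idx, drop = FALSE])
  if (any(total <= 0))
    stop("zero total power in channel(s): ",
         paste(ps$labels[total <= 0], collapse = ", "))
  rp <- sapply(seq_len(nrow(scheme)), function(b) {
    idx <- f >= scheme$f_lo[b] & f < scheme$f_hi[b]
    rowSums(ps$psd[, idx, drop = FALSE]) / total
  })
  rp <- matrix(rp, nrow = nrow(ps$psd),
               dimnames = list(ps$labels, scheme$name))
  structure(rp, class = c("band_power", "matrix"), scheme = scheme)
}
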