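#' Band-pass filter a continuous recording
#'
#' Zero-phase band-pass filtering (linear-phase Hamming-window FIR applied by
#' FFT convolution with group-delay compensation).  Zero phase matters here:
#' downstream phase-synchrony metrics must not inherit filter phase
#' distortion.  The passband ripple is below 1% and stopband attenuation
#' exceeds 40 dB one transition width outside the band.
#'
#' @param rec A continuous (single-epoch) `eeg_recording`.
#' @param f_lo,f_hi Band edges in Hz; `f_hi` must be below Nyquist.
#' @param transition Transition-band width in Hz (sets the FIR length).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, f_lo = 2, f_hi = 46, transition = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_epochs(rec) != 1)
    stop("bandpass_filter expects continuous (single-epoch) data; ",
         "filter before segmenting")
  if (f_lo <= 0 || f_hi <= f_lo) stop("need 0 < f_lo < f_hi")
  if (f_hi >= rec$fs / 2)
    stop("f_hi (", f_hi, " Hz) must be below the Nyquist frequency (",
         rec$fs / 2, " Hz)")
  h <- fir_bandpass(f_lo, f_hi, rec$fs, transition)
  x <- t(matrix(rec$data[, 1, ], nrow = n_channels(rec)))  # samples x ch
  y <- apply_fir_zerophase(x, h)
  out <- rec
  out$data <- array(t(y), dim(rec$data))
  out
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the per-sample channel mean of the output is zero.
#'
#' @param rec An `eeg_recording` with at least 2 channels.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2) stop("average reference needs >= 2 channels")
  d <- rec$data
  m <- colMeans(d)                              # epochs x samples
  out <- rec
  out$data <- d - rep(m, each = dim(d)[1])
  out
}

#' Cut a continuous recording into fixed-length epochs
#'
#' Non-overlapping epochs of `epoch_len_s` seconds; trailing samples that do
#' not fill an epoch are dropped (the count is recorded in the
#' `"dropped_samples"` attribute).
#'
#' @param rec A continuous (single-epoch) `eeg_recording`.
#' @param epoch_len_s Epoch length in seconds; `epoch_len_s * fs` must be an
#'   integer.
#' @return An epoched `eeg_recording`.
#' @export
segment_epochs <- function(rec, epoch_len_s = 1.0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_epochs(rec) != 1) stop("recording is already epoched")
  len <- epoch_len_s * rec$fs
  if (abs(len - round(len)) > 1e-9)
    stop("epoch_len_s * fs must be an integer sample count")
  len <- as.integer(round(len))
  total <- n_samples(rec)
  n_ep <- total %/% len
  if (n_ep < 1) stop("recording (", total, " samples) is shorter than one ",
                     "epoch (", len, " samples)")
  kept <- n_ep * len
  x <- rec$data[, 1, seq_len(kept), drop = FALSE]
  out <- rec
  out$data <- aperm(array(x[, 1, ], c(n_channels(rec), len, n_ep)),
                    c(1, 3, 2))
  out$epoch_len <- epoch_len_s
  attr(out, "dropped_samples") <- total - kept
  out
}

#' Reject outlier epochs by z-scored artifact metrics
#'
#' Three per-epoch metrics, each averaged over channels: signal variance,
#' peak-to-peak amplitude range, and deviation of the epoch's channel means
#' from the channel grand means.  An epoch is rejected when the z-score
#' (across epochs) of any metric exceeds `z_thresh` in absolute value;
#' "deviating" is treated as unsigned, so rejection is two-sided.
#'
#' @param rec An epoched `eeg_recording` with at least 3 epochs.
#' @param z_thresh Rejection threshold in standard deviations (default 2).
#' @return A list with `recording` (retained epochs, original order) and
#'   `report`, a `preprocess_report` holding counts, kept indices and the
#'   per-epoch metric table.
#' @export
reject_epochs_zscore <- function(rec, z_thresh = 2.0) {
  stopifnot(inherits(rec, "eeg_recording"))
  ne <- n_epochs(rec)
  if (ne < 3) stop("epoch rejection needs >= 3 epochs")
  d <- rec$data
  nc <- dim(d)[1]; ns <- dim(d)[3]
  M <- matrix(d, nc * ne)                       # (ch*epoch) x sample
  mu <- rowMeans(M)
  v <- (rowMeans(M^2) - mu^2) * ns / (ns - 1)
  rmax <- M[, 1]; rmin <- M[, 1]
  for (j in 2:ns) { rmax <- pmax(rmax, M[, j]); rmin <- pmin(rmin, M[, j]) }
  em <- matrix(mu, nc, ne)
  dev <- abs(em - rowMeans(em))
  metrics <- cbind(variance = colMeans(matrix(v, nc, ne)),
                   amplitude_range = colMeans(matrix(rmax - rmin, nc, ne)),
                   mean_deviation = colMeans(dev))
  z <- scale(metrics)
  z[is.nan(z)] <- 0                             # constant metric: no evidence
  bad <- apply(abs(z) > z_thresh, 1, any)
  if (all(bad))
    stop("all ", ne, " epochs rejected at |z| > ", z_thresh,
         "; inspect metric table")
  keep <- which(!bad)
  out <- rec
  out$data <- d[, keep, , drop = FALSE]
  report <- structure(list(n_epochs_in = ne,
                           n_epochs_rejected = sum(bad),
                           kept = keep,
                           metrics = as.data.frame(metrics),
                           z_thresh = z_thresh,
                           filter = "zero-phase FIR band-pass",
                           reference = "common average"),
                      class = "preprocess_report")
  list(recording = out, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report> %d/%d epochs rejected (|z| > %g)\n",
              x$n_epochs_rejected, x$n_epochs_in, x$z_thresh))
  invisible(x)
}
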