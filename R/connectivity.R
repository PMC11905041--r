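#' Instantaneous phase via the band-limited analytic signal
#'
#' Band-pass filters each channel (zero-phase FIR, same design contract as
#' [bandpass_filter()]) and takes the argument of the analytic signal.
#' Filtering and the Hilbert transform are applied to the continuous record
#' in a single frequency-domain pass; extract phases *before* segmenting into
#' epochs (1-s epochs are too short to band-filter cleanly in isolation) and
#' then slice with [segment_phases()].  Multi-epoch input is processed
#' epoch-by-epoch, which is only appropriate for long epochs.
#'
#' @param rec An `eeg_recording`.
#' @param band Numeric `c(f_lo, f_hi)` in Hz, within (0, fs/2).
#' @param transition FIR transition width in Hz (default 1).
#' @return A `phase_array`: list with `phases` (channel x epoch x sample,
#'   radians in (-pi, pi]), `band`, `fs`, `labels`.
#' @export
analytic_phase <- function(rec, band, transition = 1) {
  stopifnot(inherits(rec, "eeg_recording"), length(band) == 2)
  if (band[1] <= 0 || band[2] >= rec$fs / 2 || band[2] <= band[1])
    stop("band must satisfy 0 < f_lo < f_hi < fs/2")
  if (band[1] < 2 - 1e-9 || band[2] > 46 + 1e-9)
    stop("band [", band[1], ", ", band[2],
         "] lies outside the 2-46 Hz analysis range")
  d <- rec$data
  ph <- array(NA_real_, dim(d))
  for (e in seq_len(dim(d)[2])) {
    x <- t(matrix(d[, e, ], nrow = dim(d)[1]))
    z <- band_analytic(x, band[1], band[2], rec$fs, transition)
    ph[, e, ] <- t(wrap_phase(Arg(z)))
  }
  structure(list(phases = ph, band = band, fs = rec$fs, labels = rec$labels),
            class = "phase_array")
}

#' @export
print.phase_array <- function(x, ...) {
  d <- dim(x$phases)
  cat(sprintf("<phase_array> %d ch x %d epoch(s) x %d samples, band %g-%g Hz\n",
              d[1], d[2], d[3], x$band[1], x$band[2]))
  invisible(x)
}

#' @rdname analytic_phase
#' @param pa A continuous (single-epoch) `phase_array`.
#' @param epoch_len_s Epoch length in seconds.
#' @param keep Optional integer vector of epoch indices to retain (e.g. the
#'   `kept` field of a [reject_epochs_zscore()] report), so phase epochs
#'   match the epochs retained for spectral analysis.
#' @export
segment_phases <- function(pa, epoch_len_s = 1.0, keep = NULL) {
  stopifnot(inherits(pa, "phase_array"))
  if (dim(pa$phases)[2] != 1) stop("phase array is already epoched")
  len <- epoch_len_s * pa$fs
  if (abs(len - round(len)) > 1e-9)
    stop("epoch_len_s * fs must be an integer sample count")
  len <- as.integer(round(len))
  n_ep <- dim(pa$phases)[3] %/% len
  if (n_ep < 1) stop("phase array shorter than one epoch")
  nc <- dim(pa$phases)[1]
  ph <- aperm(array(pa$phases[, 1, seq_len(n_ep * len)], c(nc, len, n_ep)),
              c(1, 3, 2))
  if (!is.null(keep)) {
    if (any(keep < 1 | keep > n_ep)) stop("keep indices out of range")
    ph <- ph[, keep, , drop = FALSE]
  }
  out <- pa
  out$phases <- ph
  out
}

#' Phase-locking metrics for one channel pair
#'
#' With the complex mean `C = mean(exp(1i * (phi_a - phi_b)))`:
#' `PLV = |C|`; `iPLV = |Im C|`; `ciPLV = |Im C| / sqrt(1 - Re(C)^2)`.
#' The ciPLV denominator removes the bias that the zero-lag (real) component
#' induces on the imaginary part.  When `1 - Re(C)^2 < eps` the phase
#' difference is locked at zero lag and ciPLV is defined as 0 (perfect
#' zero-lag locking carries no lagged synchrony).
#'
#' @param phi_a,phi_b Equal-length phase series in radians (N >= 2).
#' @param eps Degeneracy guard for the ciPLV denominator.
#' @return Named numeric vector `c(plv, iplv, ciplv)`, each in `[0, 1]`.
#' @export
phase_locking <- function(phi_a, phi_b, eps = 1e-12) {
  if (length(phi_a) != length(phi_b))
    stop("phase series have different lengths (", length(phi_a), " vs ",
         length(phi_b), ")")
  if (length(phi_a) < 2) stop("need at least 2 samples")
  d <- phi_a - phi_b
  re <- mean(cos(d)); im <- mean(sin(d))
  denom2 <- 1 - re^2
  c(plv = sqrt(re^2 + im^2),
    iplv = abs(im),
    ciplv = if (denom2 < eps) 0 else abs(im) / sqrt(denom2))
}

#' All-pairs connectivity matrix
#'
#' Computes the chosen phase-locking metric for every unordered channel pair,
#' per epoch, and averages across epochs.  The diagonal is 1 for PLV and 0
#' for iPLV/ciPLV.
#'
#' @param pa A `phase_array` with at least one epoch.
#' @param metric `"ciplv"` (default), `"plv"` or `"iplv"`.
#' @param eps ciPLV degeneracy guard, see [phase_locking()].
#' @return A `connectivity_matrix`: list with symmetric `values` (channel x
#'   channel in `[0,1]`), `metric`, `band`, `labels`, `n_epochs_averaged`.
#' @export
connectivity_matrix <- function(pa, metric = c("ciplv", "plv", "iplv"),
                                eps = 1e-12) {
  stopifnot(inherits(pa, "phase_array"))
  metric <- match.arg(metric)
  ph <- pa$phases
  pl_epochs(cos(ph), sin(ph), metric, eps, pa$labels, pa$band)
}

# Shared per-epoch accumulation over unit phasors (Cc = cos(phase),
# Sc = sin(phase), each channel x epoch x sample).  Kept separate so the
# pipeline can feed normalized analytic phasors directly without a
# round-trip through atan2/cos/sin.
pl_epochs <- function(Cc, Sc, metric, eps, labels, band) {
  nc <- dim(Cc)[1]; ne <- dim(Cc)[2]; ns <- dim(Cc)[3]
  acc <- matrix(0, nc, nc)
  for (e in seq_len(ne)) {
    Ce <- t(matrix(Cc[, e, ], nrow = nc))         # sample x ch
    Se <- t(matrix(Sc[, e, ], nrow = nc))
    acc <- acc + pl_one_epoch(Ce, Se, metric, eps)
  }
  vals <- acc / ne
  vals <- (vals + t(vals)) / 2                  # enforce exact symmetry
  diag(vals) <- if (metric == "plv") 1 else 0
  dimnames(vals) <- list(labels, labels)
  structure(list(values = vals, metric = metric, band = band,
                 labels = labels, n_epochs_averaged = ne),
            class = "connectivity_matrix")
}

# one epoch, phasor components as sample x channel matrices
pl_one_epoch <- function(Ce, Se, metric, eps) {
  ns <- nrow(Ce)
  re <- (crossprod(Ce) + crossprod(Se)) / ns
  A <- crossprod(Se, Ce) / ns
  im <- A - t(A)
  switch(metric,
         plv = sqrt(re^2 + im^2),
         iplv = abs(im),
         ciplv = {
           denom2 <- 1 - re^2
           out <- abs(im) / sqrt(pmax(denom2, eps))
           out[denom2 < eps] <- 0
           out
         })
}

# continuous phasor matrices (sample x channel) sliced into epochs of `len`
# samples, restricted to `keep`; avoids materializing epoch arrays
pl_epochs_cont <- function(Ure, Uim, len, keep, metric, eps, labels, band) {
  nc <- ncol(Ure)
  acc <- matrix(0, nc, nc)
  for (e in keep) {
    rows <- ((e - 1) * len + 1):(e * len)
    acc <- acc + pl_one_epoch(Ure[rows, , drop = FALSE],
                              Uim[rows, , drop = FALSE], metric, eps)
  }
  vals <- acc / length(keep)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- if (metric == "plv") 1 else 0
  dimnames(vals) <- list(labels, labels)
  structure(list(values = vals, metric = metric, band = band,
                 labels = labels, n_epochs_averaged = length(keep)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d ch, band %g-%g Hz, %d epoch(s)\n",
              x$metric, nrow(x$values), x$band[1], x$band[2],
              x$n_epochs_averaged))
  invisible(x)
}

#' Node strength
#'
#' Mean connectivity of each electrode to all other electrodes:
#' `s_i = mean_{j != i} values[i, j]`.
#'
#' @param cm A `connectivity_matrix` (or a plain symmetric matrix).
#' @return Named numeric vector of per-electrode strengths.
#' @export
node_strength <- function(cm) {
  v <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-8)
    stop("node_strength expects a symmetric matrix")
  n <- nrow(v)
  s <- (rowSums(v) - diag(v)) / (n - 1)
  names(s) <- rownames(v)
  s
}
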