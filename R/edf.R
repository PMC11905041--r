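# Minimal European Data Format (EDF) support.  Only the original 16-bit
# continuous EDF layout is handled: ASCII headers, equal sampling rate across
# EEG signals, little-endian int16 data records scaled by the per-signal
# physical/digital calibration.  Annotation channels are dropped on read.

#' Read a European Data Format (EDF) file
#'
#' Returns the recording as a single continuous epoch, converted to
#' microvolts (signals whose physical dimension is mV or V are rescaled).
#'
#' @param path Path to an `.edf` file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stop("truncated EDF header")
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_records <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1) stop("invalid EDF signal count")
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256 * ns)
    stop("truncated EDF signal header")
  take <- function(width, from0) {
    vapply(seq_len(ns) - 1L,
           function(k) trimws(substr(sig_hdr, from0 + k * width + 1,
                                     from0 + (k + 1) * width)),
           character(1))
  }
  labels <- take(16, 0)
  units <- take(8, ns * (16 + 80))
  phys_min <- as.numeric(take(8, ns * (16 + 80 + 8)))
  phys_max <- as.numeric(take(8, ns * (16 + 80 + 8 + 8)))
  dig_min <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8)))
  dig_max <- as.numeric(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8)))
  spr <- as.integer(take(8, ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80)))
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (!any(keep)) stop("EDF file contains no signal channels")
  if (length(unique(spr[keep])) != 1)
    stop("EDF signals have differing sampling rates; not supported")
  if (is.na(rec_dur) || rec_dur <= 0) stop("invalid EDF record duration")
  fs <- spr[keep][1] / rec_dur
  rec_samples <- sum(spr)
  payload <- readBin(con, "integer", n = n_records * rec_samples, size = 2,
                     signed = TRUE, endian = "little")
  if (length(payload) < n_records * rec_samples)
    stop("truncated EDF data: expected ", n_records * rec_samples,
         " samples, got ", length(payload))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  u_scale <- ifelse(grepl("^mV$", units, ignore.case = TRUE), 1000,
                    ifelse(grepl("^V$", units, ignore.case = TRUE), 1e6, 1))
  ends <- cumsum(spr)
  starts <- c(0, utils::head(ends, -1)) + 1
  out <- matrix(NA_real_, sum(keep), n_records * spr[keep][1])
  ki <- 0L
  for (s in seq_len(ns)) {
    if (!keep[s]) next
    ki <- ki + 1L
    idx <- as.vector(outer(starts[s]:ends[s], (seq_len(n_records) - 1) *
                             rec_samples, `+`))
    out[ki, ] <- (payload[idx] * gain[s] + offset[s]) * u_scale[s]
  }
  epoched_recording(out, fs = fs, labels = labels[keep])
}

#' Write a recording as EDF (16-bit)
#'
#' Writer used for interoperability and round-trip testing.  The recording is
#' flattened to a continuous signal and quantized to the EDF digital range
#' over a symmetric physical range covering the data.
#'
#' @param rec An `eeg_recording` (values in microvolts).
#' @param path Output path.
#' @param physical_max Physical range bound in microvolts; default covers the
#'   data with 5% headroom.
#' @export
write_edf <- function(rec, path, physical_max = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- flatten_epochs(rec)
  if (is.null(physical_max))
    physical_max <- max(abs(x)) * 1.05 + .Machine$double.eps
  # header fields are 8 ASCII chars; round so the printed and applied
  # calibration agree exactly
  physical_max <- signif(physical_max, 4)
  nch <- nrow(x)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer fs")
  spr <- as.integer(round(fs))              # 1-s records
  n_records <- floor(ncol(x) / spr)
  if (n_records < 1) stop("recording shorter than one EDF record")
  x <- x[, seq_len(n_records * spr), drop = FALSE]
  # symmetric digital range -32767..32767 so that digital 0 maps exactly to
  # physical 0 (no half-step offset on round trip)
  dig <- round(x / physical_max * 32767)
  dig[dig > 32767] <- 32767
  dig[dig < -32767] <- -32767
  pad <- function(s, w) formatC(substr(s, 1, w), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("local patient", 80), pad("local recording", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(as.character(256 * (1 + nch)), 8), pad("", 44),
                pad(as.character(n_records), 8), pad("1", 8),
                pad(as.character(nch), 4))
  writeChar(hdr, con, eos = NULL)
  w <- function(vals, width) writeChar(paste0(vapply(as.character(vals),
        pad, character(1), width), collapse = ""), con, eos = NULL)
  w(rec$labels, 16)
  w(rep("active electrode", nch), 80)
  w(rep("uV", nch), 8)
  w(rep(formatC(-physical_max, format = "g", digits = 4), nch), 8)
  w(rep(formatC(physical_max, format = "g", digits = 4), nch), 8)
  w(rep("-32767", nch), 8)
  w(rep("32767", nch), 8)
  w(rep("", nch), 80)
  w(rep(spr, nch), 8)
  w(rep("", nch), 32)
  for (r in seq_len(n_records)) {
    block <- t(dig[, ((r - 1) * spr + 1):(r * spr), drop = FALSE])
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}
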