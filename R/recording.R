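#' Epoched EEG recordings
#'
#' The package's data container: a channels x epochs x samples array of EEG
#' voltage in microvolts, with sampling rate, channel labels and group
#' membership.  A continuous recording is represented as a single epoch.
#'
#' @param data Numeric array, channels x epochs x samples (a channels x
#'   samples matrix is promoted to one epoch).
#' @param fs Sampling rate in Hz.
#' @param labels Channel names, one per row of `data`.
#' @param subject_id Subject identifier string.
#' @param group Group label, conventionally `"SCZ"`, `"CON"` or `NA`.
#' @return An `eeg_recording` object.
#' @export
epoched_recording <- function(data, fs, labels, subject_id = NA_character_,
                              group = NA_character_) {
  if (is.matrix(data)) data <- array(data, c(nrow(data), 1L, ncol(data)))
  stopifnot(length(dim(data)) == 3)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar")
  if (any(!is.finite(data))) stop("data contains non-finite values")
  if (dim(data)[1] != length(labels))
    stop("channel count (", dim(data)[1], ") does not match labels (",
         length(labels), ")")
  epoch_len <- dim(data)[3] / fs
  if (abs(epoch_len * fs - round(epoch_len * fs)) > 1e-9)
    stop("epoch length times fs must be an integer sample count")
  structure(list(data = data, fs = fs, epoch_len = epoch_len,
                 labels = as.character(labels), subject_id = subject_id,
                 group = group),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_recording> %d ch x %d epoch(s) x %d samples @ %g Hz",
              d[1], d[2], d[3], x$fs))
  if (!is.na(x$subject_id)) cat("  [", x$subject_id, "/", x$group, "]", sep = "")
  cat("\n")
  invisible(x)
}

n_channels <- function(rec) dim(rec$data)[1]
n_epochs <- function(rec) dim(rec$data)[2]
n_samples <- function(rec) dim(rec$data)[3]

# channels x (epochs*samples) matrix, epochs in temporal order
flatten_epochs <- function(rec) {
  d <- dim(rec$data)
  matrix(aperm(rec$data, c(1, 3, 2)), nrow = d[1])
}

#' Read and write recordings
#'
#' The packaged on-disk format is a raw little-endian float64 matrix
#' (channel-major sample blocks) beside a JSON sidecar `<path>.json` holding
#' labels, sampling rate, epoch structure and group.  Files ending in `.edf`
#' are read as European Data Format (16-bit) instead; EDF is read-only.
#'
#' @param path File path.  `write_recording()` writes `path` and
#'   `path + ".json"`.
#' @param rec An `eeg_recording`.
#' @return `read_recording()` returns an `eeg_recording`; voltages in
#'   microvolts.
#' @export
read_recording <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  need <- c("labels", "fs", "n_channels", "n_epochs", "n_samples")
  if (!all(need %in% names(meta)))
    stop("sidecar missing field(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  if (length(meta$labels) != meta$n_channels)
    stop("sidecar label count does not match n_channels")
  n_val <- meta$n_channels * meta$n_epochs * meta$n_samples
  expected_bytes <- 8 * n_val
  if (file.info(path)$size < expected_bytes)
    stop("recording file truncated: expected ", expected_bytes, " bytes, got ",
         file.info(path)$size)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n_val, size = 8, endian = "little")
  data <- array(vals, c(meta$n_channels, meta$n_epochs, meta$n_samples))
  epoched_recording(data, fs = meta$fs, labels = meta$labels,
                    subject_id = meta$subject_id %||% NA_character_,
                    group = meta$group %||% NA_character_)
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "wb")
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(labels = rec$labels, fs = rec$fs, epoch_len = rec$epoch_len,
               n_channels = n_channels(rec), n_epochs = n_epochs(rec),
               n_samples = n_samples(rec), subject_id = rec$subject_id,
               group = rec$group, units = "uV")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
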