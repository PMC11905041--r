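# shared fixture builders (all data generated in code)

sine_recording <- function(freq = 10, dur = 10, fs = 256, n_ch = 1,
                           amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- matrix(rep(amp * sin(2 * pi * freq * t), each = n_ch), n_ch)
  epoched_recording(x, fs, paste0("ch", seq_len(n_ch)))
}

noise_recording <- function(dur = 10, fs = 256, n_ch = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_ch * dur * fs), n_ch)
  epoched_recording(x, fs, paste0("ch", seq_len(n_ch)))
}

write_montage_file <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# mid-sized montage: 2x2 grid plus an isolated far electrode
toy_montage <- function() {
  path <- write_montage_file(c("A 0 0 1",
                               "B 0.2 0 0.98",
                               "C 0 0.2 0.98",
                               "D 0.2 0.2 0.96",
                               "E 0 0 -1"))
  load_montage(path)
}

# uniform random phases as a phase_array (chance-level synchrony)
random_phase_array <- function(n_ch = 6, n_ep = 4, n_samp = 256, seed = 1) {
  set.seed(seed)
  ph <- array(runif(n_ch * n_ep * n_samp, -pi, pi), c(n_ch, n_ep, n_samp))
  structure(list(phases = ph, band = c(4, 9), fs = 256,
                 labels = paste0("ch", seq_len(n_ch))),
            class = "phase_array")
}
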