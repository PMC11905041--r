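#' Configuration for a simulated two-group resting-EEG study
#'
#' Defines the study conditions emulated by the generator: two groups
#' (default 28 vs 27 subjects), 64-channel 256-Hz recordings of 300 s,
#' narrowband cortical sources placed at montage electrodes, group-specific
#' source power multipliers, group-specific phase-lag couplings, 1/f
#' background noise, and instantaneous Gaussian spatial leakage.
#'
#' The default effect template plants (i) a theta power excess at
#' centroparietal sources (projecting maximally near CPz/Pz) in the first
#' group, (ii) an inter-hemispheric frontotemporal theta coupling at lag
#' pi/2 in the first group, and (iii) an intra-hemispheric frontoparietal
#' beta coupling in the first group, against a background of bilateral
#' occipital alpha present in both groups.
#'
#' @param n_per_group Named vector of group sizes; names are the group
#'   labels and the first group carries the planted effects.
#' @param duration_s Recording length per subject in seconds.
#' @param fs Sampling rate in Hz.
#' @param sources data.frame with columns `name`, `electrode` (anchor label
#'   in the montage), `freq` (center frequency, Hz); each source is a
#'   narrowband oscillator at `freq` +/- 1 Hz.
#' @param power_effects data.frame with columns `source`, `group`, `mult`:
#'   source power multiplier applied in that group (1 = no effect).
#' @param couplings data.frame with columns `source_i`, `source_j`, `lag`
#'   (radians in (-pi, pi]), `strength` (in `[0, 1]`, fraction of phase
#'   variance locked), `group` (a group label, or `"both"`).
#' @param noise_exponent Spectral exponent of the 1/f channel noise.
#' @param snr Band-limited (2-46 Hz) source-to-noise variance ratio,
#'   averaged over channels.
#' @param subject_sd SD of the per-subject log-normal source amplitude
#'   factor (between-subject variability; drives realistic effect sizes).
#' @param leakage_width Spatial Gaussian leakage width (chord distance on
#'   the unit sphere); mixing is strictly instantaneous.
#' @param phase_walk_sd Per-sample SD (radians) of the random-walk phase
#'   noise that dilutes couplings with `strength < 1`.
#' @param sensor_rms_uV Target RMS amplitude of the sensor signals.
#' @param montage Montage used for source anchors and projection.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_per_group = c(SCZ = 28, CON = 27),
                         duration_s = 300, fs = 256,
                         sources = default_sources(),
                         power_effects = default_power_effects(),
                         couplings = default_couplings(),
                         noise_exponent = 1, snr = 1,
                         subject_sd = 0.4, leakage_width = 0.35,
                         phase_walk_sd = 0.2, sensor_rms_uV = 20,
                         montage = biosemi64_montage(), seed = 1) {
  stopifnot(length(n_per_group) == 2, !is.null(names(n_per_group)),
            duration_s > 0, fs > 0, snr > 0, leakage_width > 0)
  if (any(n_per_group <= 0))
    stop("group(s) with no subjects: ",
         paste(names(n_per_group)[n_per_group <= 0], collapse = ", "))
  sources <- as.data.frame(sources)
  couplings <- as.data.frame(couplings)
  power_effects <- as.data.frame(power_effects)
  if (nrow(sources)) {
    stopifnot(all(c("name", "electrode", "freq") %in% names(sources)))
    missing_el <- setdiff(sources$electrode, montage$labels)
    if (length(missing_el))
      stop("source anchor electrode(s) not in montage: ",
           paste(missing_el, collapse = ", "))
  }
  if (nrow(couplings)) {
    bad <- setdiff(c(couplings$source_i, couplings$source_j), sources$name)
    if (length(bad))
      stop("coupling references unknown source(s): ",
           paste(bad, collapse = ", "))
    if (any(couplings$source_i == couplings$source_j))
      stop("coupling must join two distinct sources")
    stopifnot(all(couplings$strength >= 0 & couplings$strength <= 1),
              all(couplings$lag > -pi & couplings$lag <= pi))
  }
  if (nrow(power_effects)) {
    bad <- setdiff(power_effects$source, sources$name)
    if (length(bad))
      stop("power effect references unknown source(s): ",
           paste(bad, collapse = ", "))
    stopifnot(all(power_effects$mult > 0))
  }
  structure(list(n_per_group = n_per_group, duration_s = duration_s, fs = fs,
                 sources = sources, power_effects = power_effects,
                 couplings = couplings, noise_exponent = noise_exponent,
                 snr = snr, subject_sd = subject_sd,
                 leakage_width = leakage_width,
                 phase_walk_sd = phase_walk_sd,
                 sensor_rms_uV = sensor_rms_uV,
                 montage = montage, seed = seed),
            class = "study_config")
}

#' @rdname study_config
#' @export
default_sources <- function() {
  data.frame(
    name = c("cpz_theta", "pz_theta", "ft7_theta", "ft8_theta",
             "f4_beta", "p4_beta", "o1_alpha", "o2_alpha"),
    electrode = c("CPz", "Pz", "FT7", "FT8", "F4", "P4", "O1", "O2"),
    freq = c(6, 6, 6, 6, 20, 20, 10, 10),
    amplitude = c(0.7, 0.7, 0.7, 0.7, 0.8, 0.8, 1.4, 1.4),
    stringsAsFactors = FALSE)
}

#' @rdname study_config
#' @export
default_power_effects <- function(theta_mult = 2.2) {
  data.frame(source = c("cpz_theta", "pz_theta"),
             group = "SCZ", mult = theta_mult, stringsAsFactors = FALSE)
}

#' @rdname study_config
#' @param theta_mult Theta source power multiplier for the first group.
#' @export
default_couplings <- function() {
  data.frame(source_i = c("ft7_theta", "f4_beta"),
             source_j = c("ft8_theta", "p4_beta"),
             lag = pi / 2, strength = 0.7, group = "SCZ",
             stringsAsFactors = FALSE)
}

#' Simulate the cortical sources of one subject
#'
#' Each source is a narrowband oscillator `a_k(t) cos(phi_k(t))` obtained
#' from Gaussian noise band-filtered at its center frequency +/- 1 Hz.  For
#' each coupling active in `group`, the phase of the target source is
#' replaced by `phi_i(t) + lag + (1 - strength) * random walk`, so pairwise
#' synchrony increases monotonically with `strength` (exact lag at
#' strength 1, free-running at strength 0).  Group power multipliers and the
#' per-subject log-normal amplitude factors are applied here.
#'
#' @param config A `study_config`.
#' @param group Group label (must match `names(config$n_per_group)`).
#' @param seed Per-subject RNG seed.
#' @return A `source_set`: list with `signals` (source x sample), `positions`
#'   (anchor electrode unit vectors), `center_freqs`, `fs`.
#' @export
simulate_sources <- function(config, group, seed) {
  stopifnot(inherits(config, "study_config"))
  if (!group %in% c(names(config$n_per_group), "both"))
    stop("unknown group: ", group)
  set.seed(seed)
  n <- round(config$duration_s * config$fs)
  src <- config$sources
  K <- nrow(src)
  if (K == 0) {
    return(structure(list(signals = matrix(0, 0, n),
                          positions = matrix(0, 0, 3),
                          center_freqs = numeric(0), fs = config$fs),
                     class = "source_set"))
  }
  base <- matrix(stats::rnorm(n * K), n, K)
  Z <- matrix(complex(real = 0), n, K)
  m <- length(fir_bandpass(4, 6, config$fs))     # shared tap count
  pre <- fft_prepare(base, m)
  for (f0 in unique(src$freq)) {
    cols <- which(src$freq == f0)
    Z[, cols] <- fft_apply(pre, fir_bandpass(f0 - 1, f0 + 1, config$fs),
                           analytic = TRUE, cols = cols)
  }
  sig <- Re(Z)
  cp <- config$couplings
  if (nrow(cp)) {
    active <- cp$group == group | cp$group == "both"
    for (r in which(active)) {
      i <- match(cp$source_i[r], src$name)
      j <- match(cp$source_j[r], src$name)
      walk <- cumsum(stats::rnorm(n, 0, config$phase_walk_sd))
      phi_j <- Arg(Z[, i]) + cp$lag[r] + (1 - cp$strength[r]) * walk
      sig[, j] <- Mod(Z[, j]) * cos(phi_j)
    }
  }
  # unit variance per source, then nominal, group and subject scaling
  sdv <- apply(sig, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sig <- sweep(sig, 2, sdv, "/")
  amp <- if ("amplitude" %in% names(src)) src$amplitude else rep(1, K)
  pe <- config$power_effects
  if (nrow(pe)) {
    for (r in which(pe$group == group | pe$group == "both")) {
      k <- match(pe$source[r], src$name)
      amp[k] <- amp[k] * sqrt(pe$mult[r])
    }
  }
  amp <- amp * exp(stats::rnorm(K, 0, config$subject_sd))
  sig <- sweep(sig, 2, amp, "*")
  pos <- config$montage$positions[match(src$electrode,
                                        config$montage$labels), ,
                                  drop = FALSE]
  structure(list(signals = t(sig), positions = pos,
                 center_freqs = src$freq, fs = config$fs),
            class = "source_set")
}

#' Project sources to the scalp under zero-lag leakage
#'
#' Sensor signals are `M %*% sources + pink noise`, with Gaussian mixing
#' weights `M[e, k] = exp(-d(e, k)^2 / (2 leakage_width^2))` in chord
#' distance.  Mixing is strictly instantaneous (same-sample), so it can
#' induce zero-lag but never lagged correlations between sensors -- the
#' property that makes ciPLV leakage-robust and PLV not.  Channel noise is
#' independent 1/f noise scaled so that the channel-average 2-46 Hz
#' source-to-noise variance ratio equals `config$snr`.  Noise is drawn from
#' the current RNG state (call after [simulate_sources()] under the subject
#' seed for reproducibility).
#'
#' @param sources A `source_set`.
#' @param montage The montage to project onto.
#' @param config The `study_config`.
#' @return A continuous `eeg_recording` (microvolts).
#' @export
project_to_sensors <- function(sources, montage, config) {
  stopifnot(inherits(sources, "source_set"), inherits(montage, "montage"))
  nch <- length(montage$labels)
  K <- nrow(sources$signals)
  n <- if (K > 0) ncol(sources$signals) else
    round(config$duration_s * config$fs)
  noise <- t(pink_noise(n, nch, config$fs, config$noise_exponent))
  if (K > 0) {
    D2 <- outer(rowSums(montage$positions^2), rowSums(sources$positions^2),
                `+`) - 2 * montage$positions %*% t(sources$positions)
    M <- exp(-pmax(D2, 0) / (2 * config$leakage_width^2))
    X <- M %*% sources$signals
    # Noise scaled against the *baseline* expected source variance (nominal
    # amplitudes, no group multiplier, no subject factor), so that group
    # effects and subject variability act only through their sources and
    # never modulate the background -- a per-subject empirical SNR match
    # would leak planted local effects into every channel's relative power.
    amp0 <- if ("amplitude" %in% names(config$sources))
      config$sources$amplitude else rep(1, K)
    v_sig_base <- mean((M^2) %*% amp0^2)
    n_len <- ncol(noise)
    v_noise_band <- expected_pink_var(n_len, config) *
      pink_band_frac(config)
    noise_scale <- sqrt(v_sig_base / (config$snr * v_noise_band))
    Y <- X + noise * noise_scale
  } else {
    Y <- noise
  }
  g <- config$sensor_rms_uV / sqrt(mean(rowMeans(Y^2)))
  epoched_recording(Y * g, fs = config$fs, labels = montage$labels)
}

# expected in-band variance fraction of the pink noise spectrum (analytic,
# avoids refiltering); cached per (n, fs, exponent) would be overkill
pink_band_frac <- function(config) {
  n <- round(config$duration_s * config$fs)
  freqs <- seq(0, config$fs - config$fs / n, by = config$fs / n)
  f_fold <- pmin(freqs, config$fs - freqs)
  amp2 <- ifelse(f_fold > 0, f_fold^(-config$noise_exponent), 0)
  in_band <- f_fold >= 2 & f_fold < 46
  sum(amp2[in_band]) / sum(amp2)
}

# expected total variance of one pink_noise channel of length n
expected_pink_var <- function(n, config) {
  freqs <- seq(0, config$fs - config$fs / n, by = config$fs / n)
  f_fold <- pmin(freqs, config$fs - freqs)
  amp2 <- ifelse(f_fold > 0, f_fold^(-config$noise_exponent), 0)
  sum(amp2) / n
}

#' Simulate a full two-group study
#'
#' Generates all subjects of both groups under per-subject seeds derived
#' from the master seed, together with the ground-truth effect map that the
#' analysis pipeline should recover.
#'
#' @param config A `study_config`; `config$n_per_group` must both be >= 2.
#' @return List with `recordings` (named list of per-group lists of
#'   `eeg_recording`) and `truth` (see [ground_truth()]).
#' @export
simulate_group_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (any(config$n_per_group < 2))
    stop("need at least 2 subjects per group for group statistics")
  plan <- subject_plan(config)
  recs <- lapply(split(plan, plan$group), function(pg) {
    lapply(seq_len(nrow(pg)), function(i) {
      s <- simulate_sources(config, pg$group[i], pg$seed[i])
      rec <- project_to_sensors(s, config$montage, config)
      rec$subject_id <- pg$id[i]
      rec$group <- pg$group[i]
      rec
    })
  })
  recs <- recs[names(config$n_per_group)]          # stable group order
  list(recordings = recs, truth = ground_truth(config))
}

# Deterministic per-subject seeds and ids from the master seed.
subject_plan <- function(config) {
  groups <- names(config$n_per_group)
  group <- rep(groups, config$n_per_group)
  id <- unlist(lapply(groups, function(g)
    sprintf("%s%02d", g, seq_len(config$n_per_group[[g]]))))
  set.seed(config$seed)
  seed <- sample.int(.Machine$integer.max - 1L, length(group))
  data.frame(group = group, id = id, seed = seed, stringsAsFactors = FALSE)
}

#' Ground truth of the planted effects
#'
#' `power_effect`: data.frame of electrodes expected to show a group power
#' difference (electrodes within one leakage width of a boosted source),
#' with band and sign (+1 means first group > second group).
#' `edge_effect`: data.frame of planted connectivity edges (anchor electrode
#' pair, band, sign).
#'
#' @param config A `study_config`.
#' @return List with `power_effect` and `edge_effect` data.frames.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "study_config"))
  g1 <- names(config$n_per_group)[1]
  scheme <- band_scheme()
  band_of <- function(f) {
    i <- which(scheme$f_lo <= f & f < scheme$f_hi)
    if (!length(i)) NA_character_ else scheme$name[i]
  }
  power_effect <- data.frame(electrode = character(0), band = character(0),
                             sign = integer(0), stringsAsFactors = FALSE)
  pe <- config$power_effects
  if (nrow(pe)) {
    for (r in which(pe$mult != 1 & pe$group != "both")) {
      k <- match(pe$source[r], config$sources$name)
      anchor <- config$montage$positions[
        match(config$sources$electrode[k], config$montage$labels), ]
      d <- sqrt(rowSums(sweep(config$montage$positions, 2, anchor)^2))
      els <- config$montage$labels[d <= config$leakage_width]
      sgn <- if (pe$group[r] == g1) 1L else -1L
      if (pe$mult[r] < 1) sgn <- -sgn
      power_effect <- rbind(power_effect,
        data.frame(electrode = els, band = band_of(config$sources$freq[k]),
                   sign = sgn, stringsAsFactors = FALSE))
    }
    power_effect <- unique(power_effect)
  }
  edge_effect <- data.frame(electrode_i = character(0),
                            electrode_j = character(0),
                            band = character(0), sign = integer(0),
                            stringsAsFactors = FALSE)
  cp <- config$couplings
  if (nrow(cp)) {
    for (r in which(cp$group != "both" & cp$strength > 0)) {
      i <- match(cp$source_i[r], config$sources$name)
      j <- match(cp$source_j[r], config$sources$name)
      edge_effect <- rbind(edge_effect, data.frame(
        electrode_i = config$sources$electrode[i],
        electrode_j = config$sources$electrode[j],
        band = band_of(config$sources$freq[i]),
        sign = if (cp$group[r] == g1) 1L else -1L,
        stringsAsFactors = FALSE))
    }
  }
  list(power_effect = power_effect, edge_effect = edge_effect)
}
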