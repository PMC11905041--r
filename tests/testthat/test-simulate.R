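quick_config <- function(...) {
  study_config(duration_s = 30, ...)
}

source_pair_ciplv <- function(cfg, seed, s1 = "ft7_theta", s2 = "ft8_theta") {
  s <- simulate_sources(cfg, "SCZ", seed)
  i <- match(s1, cfg$sources$name); j <- match(s2, cfg$sources$name)
  zi <- eegsync:::band_analytic(s$signals[i, ], 5, 7, cfg$fs)
  zj <- eegsync:::band_analytic(s$signals[j, ], 5, 7, cfg$fs)
  mid <- 1025:(ncol(s$signals) - 1024)
  unname(phase_locking(Arg(zj)[mid], Arg(zi)[mid])["ciplv"])
}

pair_cfg <- function(strength, dur = 30) {
  study_config(duration_s = dur, subject_sd = 0,
    couplings = data.frame(source_i = "ft7_theta", source_j = "ft8_theta",
                           lag = pi / 2, strength = strength, group = "SCZ"))
}

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- quick_config(seed = 4)
  s1 <- simulate_sources(cfg, "SCZ", 77)
  s2 <- simulate_sources(cfg, "SCZ", 77)
  expect_identical(s1, s2)
  set.seed(1); r1 <- project_to_sensors(s1, cfg$montage, cfg)
  set.seed(1); r2 <- project_to_sensors(s2, cfg$montage, cfg)
  expect_identical(r1$data, r2$data)
})

test_that("full-strength pi/2 coupling locks the source pair", {
  expect_gt(source_pair_ciplv(pair_cfg(1), 5), 0.9)
})

test_that("zero-strength coupling sits at the uncoupled chance level", {
  coupled <- sapply(1:4, function(s) source_pair_ciplv(pair_cfg(0), s))
  uncoupled <- sapply(1:4, function(s)
    source_pair_ciplv(quick_config(subject_sd = 0,
      couplings = data.frame()[0, ]), s))
  expect_lt(mean(coupled), 0.15)
  expect_lt(abs(mean(coupled) - mean(uncoupled)), 0.1)
})

test_that("estimated synchrony increases monotonically with coupling strength", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- sapply(grid, function(st)
    mean(sapply(1:5, function(s) source_pair_ciplv(pair_cfg(st), s))))
  expect_true(cor(grid, means, method = "spearman") >= 0.9 - 1e-8)
})

test_that("coupling validation rejects unknown sources and bad parameters", {
  expect_error(study_config(couplings = data.frame(
    source_i = "nope", source_j = "pz_theta", lag = 1, strength = 0.5,
    group = "SCZ")), "unknown source")
  expect_error(study_config(couplings = data.frame(
    source_i = "pz_theta", source_j = "pz_theta", lag = 1, strength = 0.5,
    group = "SCZ")), "distinct")
  expect_error(study_config(power_effects = data.frame(
    source = "nope", group = "SCZ", mult = 2)), "unknown source")
})

test_that("zero-lag mixing inflates PLV but not ciPLV above the noise floor", {
  one_src <- study_config(duration_s = 30, snr = 5, subject_sd = 0,
    sources = data.frame(name = "s1", electrode = "Cz", freq = 6,
                         amplitude = 1),
    power_effects = data.frame()[0, ], couplings = data.frame()[0, ])
  noise_only <- study_config(duration_s = 30,
    sources = data.frame(name = character(0), electrode = character(0),
                         freq = numeric(0)),
    power_effects = data.frame()[0, ], couplings = data.frame()[0, ])
  stats_for <- function(cfg, seed) {
    set.seed(seed)
    rec <- project_to_sensors(simulate_sources(cfg, "SCZ", seed),
                              cfg$montage, cfg)
    # whole-record estimate: the long series keeps the chance floor low
    pa <- analytic_phase(rec, c(4, 9))
    list(plv = connectivity_matrix(pa, "plv")$values,
         ci = connectivity_matrix(pa, "ciplv")$values)
  }
  m <- stats_for(one_src, 2)
  n <- stats_for(noise_only, 3)
  # restrict to electrodes where the mixed source dominates the noise
  mon <- one_src$montage
  near <- which(sqrt(colSums((t(mon$positions) -
                                mon$positions[match("Cz", mon$labels), ])^2))
                < 0.5)
  off <- upper.tri(m$plv[near, near])
  expect_gt(mean(m$plv[near, near][off]) - mean(n$plv[near, near][off]),
            0.2)                                        # PLV inflated
  expect_lt(abs(mean(m$ci[near, near][off]) - mean(n$ci[near, near][off])),
            0.05)                                       # ciPLV is not
})

test_that("noise-only sensors show the configured 1/f spectral slope", {
  cfg <- study_config(duration_s = 60, noise_exponent = 1,
    sources = data.frame(name = character(0), electrode = character(0),
                         freq = numeric(0)),
    power_effects = data.frame()[0, ], couplings = data.frame()[0, ])
  set.seed(6)
  rec <- project_to_sensors(simulate_sources(cfg, "CON", 6), cfg$montage, cfg)
  ps <- welch_psd(rec)
  sel <- ps$freqs >= 2 & ps$freqs < 46
  slope <- coef(lm(log(colMeans(ps$psd)[sel]) ~ log(ps$freqs[sel])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.15)
})

test_that("group studies have the configured shape and ground truth", {
  cfg <- study_config(n_per_group = c(SCZ = 2, CON = 2), duration_s = 6,
                      seed = 9)
  sim <- simulate_group_study(cfg)
  expect_named(sim$recordings, c("SCZ", "CON"))
  expect_length(sim$recordings$SCZ, 2)
  expect_equal(dim(sim$recordings$CON[[2]]$data), c(64, 1, 6 * 256))
  expect_true("Pz" %in% sim$truth$power_effect$electrode)
  expect_true(all(sim$truth$power_effect$band == "theta"))
  expect_equal(sim$truth$edge_effect$electrode_i, c("FT7", "F4"))
  expect_equal(sim$truth$edge_effect$band, c("theta", "beta"))

  expect_error(study_config(n_per_group = c(SCZ = 0, CON = 5)),
               "SCZ")
  expect_error(simulate_group_study(
    study_config(n_per_group = c(SCZ = 1, CON = 5))), "at least 2")
})

test_that("a no-effect configuration has an empty ground truth", {
  cfg <- study_config(power_effects = data.frame()[0, ],
                      couplings = data.frame()[0, ])
  truth <- ground_truth(cfg)
  expect_equal(nrow(truth$power_effect), 0)
  expect_equal(nrow(truth$edge_effect), 0)
})

test_that("the planted theta excess reaches the scalp at Pz", {
  # subject variability disabled isolates the planted mechanism
  cfg <- study_config(n_per_group = c(SCZ = 2, CON = 2), duration_s = 30,
                      subject_sd = 0, seed = 13)
  sim <- simulate_group_study(cfg)
  rp_pz <- function(rec) {
    pre <- rereference_average(rec)
    ep <- segment_epochs(bandpass_filter(pre, 2, 46), 1)
    rp <- relative_band_power(welch_psd(ep))
    rp["Pz", "theta"]
  }
  scz <- mean(sapply(sim$recordings$SCZ, rp_pz))
  con <- mean(sapply(sim$recordings$CON, rp_pz))
  expect_gt(scz, con)
})
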