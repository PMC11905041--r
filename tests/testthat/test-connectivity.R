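test_that("analytic phase advances at the oscillation frequency", {
  fs <- 256
  rec <- sine_recording(10, dur = 10)
  pa <- analytic_phase(rec, c(9, 14))
  ph <- pa$phases[1, 1, ]
  mid <- 1025:(length(ph) - 1024)
  slope <- mean(eegsync:::wrap_phase(diff(ph[mid]))) * fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01 * 2 * pi * 10)
  expect_true(all(ph > -pi & ph <= pi))
})

test_that("identical channels have zero phase difference; lagged copies pi/2", {
  fs <- 256
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  set.seed(3)
  base <- as.vector(eegsync:::apply_fir_zerophase(rnorm(length(t)),
            eegsync:::fir_bandpass(9, 11, fs)))
  rec <- epoched_recording(rbind(base, base), fs, c("a", "b"))
  pa <- analytic_phase(rec, c(9, 14))
  expect_lt(max(abs(pa$phases[1, 1, ] - pa$phases[2, 1, ])), 1e-9)

  lag <- round(fs / 10 / 4)                        # quarter cycle at 10 Hz
  n <- length(base)
  shifted <- c(base[(n - lag + 1):n], base[1:(n - lag)])  # delayed copy
  rec2 <- epoched_recording(rbind(base, shifted), fs, c("a", "b"))
  pa2 <- analytic_phase(rec2, c(9, 14))
  mid <- 1025:(length(t) - 1024)
  dphi <- eegsync:::wrap_phase(pa2$phases[1, 1, mid] - pa2$phases[2, 1, mid])
  expect_equal(mean(dphi), 2 * pi * 10 * lag / fs, tolerance = 0.05)
})

test_that("phase_locking matches its closed forms", {
  expect_equal(phase_locking(rep(pi / 2, 100), rep(0, 100)),
               c(plv = 1, iplv = 1, ciplv = 1))
  expect_equal(phase_locking(rep(0.3, 100), rep(0.3, 100)),
               c(plv = 1, iplv = 0, ciplv = 0))
  d <- rep(c(0, pi / 2), 50)
  got <- phase_locking(d, rep(0, 100))
  expect_equal(unname(got["plv"]), sqrt(0.5), tolerance = 1e-12)
  expect_equal(unname(got["iplv"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(got["ciplv"]), 0.5 / sqrt(0.75), tolerance = 1e-12)
  expect_error(phase_locking(1:5, 1:4), "length")
})

test_that("phase_locking is symmetric and ciPLV >= iPLV unless Re C = 0", {
  set.seed(11)
  for (k in 1:20) {
    a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
    ab <- phase_locking(a, b); ba <- phase_locking(b, a)
    expect_equal(ab, ba, tolerance = 1e-12)
    re <- mean(cos(a - b))
    if (abs(re) > 1e-8) expect_gt(ab[["ciplv"]], ab[["iplv"]])
  }
  # equality when the real part vanishes by construction
  d <- rep(c(pi / 2, -pi / 2, pi / 2, pi / 2), 50)  # Re C = 0
  pl <- phase_locking(d, rep(0, 200))
  expect_equal(pl[["ciplv"]], pl[["iplv"]], tolerance = 1e-12)
})

test_that("connectivity matrices: mixtures, chance level, symmetry", {
  fs <- 256
  set.seed(21)
  src <- rnorm(10 * fs)
  mix <- c(1, -0.5, 0.25, 2, -3, 0.8)
  rec <- epoched_recording(outer(mix, src), fs, paste0("ch", 1:6))
  pa <- segment_phases(analytic_phase(rec, c(4, 9)), 1)
  plv <- connectivity_matrix(pa, "plv")$values
  ci <- connectivity_matrix(pa, "ciplv")$values
  off <- upper.tri(plv)
  expect_true(all(plv[off] > 1 - 1e-9))
  expect_true(all(ci[off] == 0))
  expect_equal(ci, t(ci))
  expect_equal(unname(diag(plv)), rep(1, 6))
  expect_equal(unname(diag(ci)), rep(0, 6))

  # iid random phases sit near the estimator chance floor
  cm <- connectivity_matrix(random_phase_array(), "ciplv")$values
  expect_lt(mean(cm[upper.tri(cm)]), 0.1)
})

test_that("all metrics are invariant to per-channel amplitude scaling", {
  rec <- noise_recording(dur = 6, n_ch = 4, seed = 5)
  pa0 <- segment_phases(analytic_phase(rec, c(9, 14)), 1)
  base <- lapply(c("plv", "iplv", "ciplv"),
                 function(m) connectivity_matrix(pa0, m)$values)
  for (f in c(0.1, 10, 1000)) {
    rec2 <- rec
    rec2$data[2, , ] <- rec2$data[2, , ] * f
    pa2 <- segment_phases(analytic_phase(rec2, c(9, 14)), 1)
    got <- lapply(c("plv", "iplv", "ciplv"),
                  function(m) connectivity_matrix(pa2, m)$values)
    for (k in 1:3)
      expect_lt(max(abs(got[[k]] - base[[k]])), 1e-9)
  }
})

test_that("node strength averages off-diagonal connectivity", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.9
  v[1, 3] <- v[3, 1] <- 0.1
  v[2, 3] <- v[3, 2] <- 0.5
  expect_equal(unname(node_strength(v)), c(0.5, 0.7, 0.3))
  allhalf <- matrix(0.5, 4, 4); diag(allhalf) <- 0
  expect_equal(unname(node_strength(allhalf)), rep(0.5, 4))
  expect_equal(unname(node_strength(matrix(0, 3, 3))), rep(0, 3))
  expect_error(node_strength(matrix(1:9, 3)), "symmetric")
})
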