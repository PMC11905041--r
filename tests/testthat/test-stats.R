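# brute-force oracles implemented independently of the package internals

oracle_perm_p <- function(a, b) {
  x <- c(a, b); n <- length(x); nA <- length(a)
  tstat <- function(ia) {
    xa <- x[ia]; xb <- x[-ia]
    sp2 <- ((length(xa) - 1) * var(xa) + (length(xb) - 1) * var(xb)) /
      (n - 2)
    (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / length(xa) + 1 / length(xb)))
  }
  t_obs <- tstat(seq_len(nA))
  combs <- combn(n, nA)
  ts <- apply(combs, 2, tstat)
  mean(abs(ts) >= abs(t_obs) - 1e-12)
}

oracle_tau_b <- function(x, y) {
  n <- length(x); C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  ties <- function(v) sum(sapply(unique(v), function(u)
    choose(sum(v == u), 2)))
  n0 <- choose(n, 2)
  (C - D) / sqrt((n0 - ties(x)) * (n0 - ties(y)))
}

oracle_bh <- function(p) {
  m <- length(p); o <- order(p); adj <- numeric(m)
  sorted <- p[o]
  run <- Inf
  for (k in m:1) {
    run <- min(run, sorted[k] * m / k)
    adj[k] <- min(run, 1)
  }
  adj[order(o)]
}

test_that("pooled t from summary statistics matches analytic cases", {
  expect_equal(pooled_t_from_summary(1, 1, 2, 0, 1, 2), 1)
  expect_equal(pooled_t_from_summary(5, 2, 10, 5, 2, 10), 0)
  expect_equal(pooled_t_from_summary(3, 0, 4, 3, 0, 5), 0)
  expect_error(pooled_t_from_summary(3, 0, 4, 4, 0, 5), "undefined")
  # published-style demographic row: means/SDs with n = 28/27
  expect_equal(pooled_t_from_summary(23.54, 3.42, 28, 27.11, 1.89, 27),
               -4.78, tolerance = 0.015)
})

test_that("Cohen's d matches hand computation", {
  expect_equal(cohens_d(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
  set.seed(1)
  x <- rnorm(2000) + 1; y <- rnorm(2000)
  expect_equal(cohens_d(x, y), 1, tolerance = 0.1)
})

test_that("permutation test agrees with exhaustive enumeration", {
  r <- permutation_test(c(1, 2, 3), c(1, 2, 3), n_perm = 100)
  expect_true(r$exhaustive)
  expect_equal(r$p, 1)

  r2 <- permutation_test(c(10, 11, 12), c(0, 1, 2), n_perm = 100)
  expect_true(r2$exhaustive)
  expect_equal(r2$p, 2 / 20)

  set.seed(33)
  for (k in 1:5) {
    a <- rnorm(4); b <- rnorm(3, 0.5)
    expect_equal(permutation_test(a, b, n_perm = 50)$p, oracle_perm_p(a, b))
  }
  expect_equal(permutation_test(rep(2, 5), rep(2, 4))$p, 1)
})

test_that("permutation p is invariant to affine rescaling and group-internal order", {
  set.seed(9)
  a <- rnorm(4); b <- rnorm(4)
  p0 <- permutation_test(a, b, n_perm = 100)$p     # exhaustive (C(8,4)=70)
  expect_equal(permutation_test(3 * a + 10, 3 * b + 10, n_perm = 100)$p, p0)
  expect_equal(permutation_test(rev(a), sample(b), n_perm = 100)$p, p0)
  # Monte-Carlo path: seeded determinism
  a2 <- rnorm(8); b2 <- rnorm(7)
  expect_equal(permutation_test(a2, b2, n_perm = 499, seed = 5)$p,
               permutation_test(a2, b2, n_perm = 499, seed = 5)$p)
})

test_that("BH adjustment matches the step-up oracle and p.adjust", {
  p <- c(0.005, 0.04, 0.04, 0.05)
  got <- fdr_bh(p)
  expect_equal(got$p_adj, c(0.02, 0.05, 0.05, 0.05))
  expect_equal(got$p_adj, oracle_bh(p))

  expect_equal(fdr_bh(rep(0.05, 10))$p_adj, rep(0.05, 10))
  expect_equal(fdr_bh(0.012)$p_adj, 0.012)
  expect_identical(fdr_bh(numeric(0))$p_adj, numeric(0))

  set.seed(2)
  pr <- runif(40)^2
  expect_equal(fdr_bh(pr)$p_adj, oracle_bh(pr))
  # BH rejections contain the Bonferroni rejections at the same level
  bonf <- pr <= 0.05 / length(pr)
  expect_true(all(fdr_bh(pr)$reject[bonf]))
})

test_that("rank correlations match oracles and closed forms", {
  x <- 1:6
  expect_equal(spearman_rho(x, 2 * x + 3), 1)
  expect_equal(kendall_tau_b(x, 2 * x + 3), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_equal(kendall_tau_b(x, rev(x)), -1)

  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)

  set.seed(14)
  for (k in 1:5) {
    x <- sample(1:4, 10, replace = TRUE)     # heavy ties
    y <- sample(1:4, 10, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau_b(x, y), oracle_tau_b(x, y))
  }
  # cross-check against stats::cor on untied data
  set.seed(15)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(kendall_tau_b(x, y), cor(x, y, method = "kendall"))
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  expect_error(spearman_rho(rep(1, 5), 1:5), "zero rank")
})

test_that("IQR fences flag only genuine outliers", {
  v <- c(1:9, 100)
  expect_equal(which(iqr_outliers(v)), 10)
  expect_false(any(iqr_outliers(rep(3, 6))))
  expect_false(any(iqr_outliers(1:10)))
  # oracle fence computation
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_equal(iqr_outliers(v), v < q[1] - 1.5 * diff(q) |
                                v > q[2] + 1.5 * diff(q))
})

test_that("edgewise test reduces to the scalar test on a single edge", {
  set.seed(20)
  mk <- function(v) {
    m <- matrix(c(0, v, v, 0), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    structure(list(values = m, metric = "ciplv", band = c(4, 9),
                   labels = c("a", "b"), n_epochs_averaged = 10),
              class = "connectivity_matrix")
  }
  va <- rnorm(8, 0.5, 0.1); vb <- rnorm(7, 0.3, 0.1)
  es <- edgewise_group_test(lapply(va, mk), lapply(vb, mk),
                            n_perm = 499, seed = 3)
  ref <- permutation_test(va, vb, n_perm = 499, seed = 3)
  expect_equal(nrow(es), 1)
  expect_equal(es$p, ref$p)
  expect_equal(es$t, ref$t_obs)
  expect_equal(es$d, cohens_d(va, vb))
  expect_error(edgewise_group_test(lapply(va, mk), lapply(vb, function(v) {
    m <- mk(v); m$band <- c(9, 14); m
  }), n_perm = 99), "band")
})

test_that("copied groups yield no significant edges", {
  set.seed(4)
  mats <- lapply(rnorm(6, 0.4, 0.05), function(v) {
    vals <- matrix(0.2, 3, 3); diag(vals) <- 0
    vals[1, 2] <- vals[2, 1] <- v
    structure(list(values = vals, metric = "ciplv", band = c(4, 9),
                   labels = letters[1:3], n_epochs_averaged = 5),
              class = "connectivity_matrix")
  })
  es <- edgewise_group_test(mats, mats, n_perm = 299, seed = 8)
  expect_false(any(es$significant))
  expect_true(all(es$p == 1))
})

test_that("cluster test finds planted clusters and respects adjacency", {
  mon <- biosemi64_montage()
  adj <- build_adjacency(mon)
  nb <- eegsync:::neighbor_list(adj)
  pz <- match("Pz", mon$labels)
  planted <- c(pz, nb[[pz]])
  set.seed(31)
  A <- matrix(rnorm(64 * 28), 64); B <- matrix(rnorm(64 * 27), 64)
  A[planted, ] <- A[planted, ] + 1.2
  cr <- cluster_permutation_test(A, B, adj, n_perm = 499, seed = 17)
  best <- cr$clusters[[1]]
  expect_lt(best$p, 0.05)
  expect_true("Pz" %in% best$members)
  expect_equal(best$sign, "A>B")
  # determinism
  cr2 <- cluster_permutation_test(A, B, adj, n_perm = 499, seed = 17)
  expect_equal(vapply(cr2$clusters, `[[`, numeric(1), "p"),
               vapply(cr$clusters, `[[`, numeric(1), "p"))
})

test_that("an isolated supra-threshold electrode forms a singleton cluster", {
  mon <- toy_montage()                     # E is isolated from A-D
  suppressWarnings(adj <- build_adjacency(mon, 0.4))
  set.seed(41)
  A <- matrix(rnorm(5 * 12), 5); B <- matrix(rnorm(5 * 12), 5)
  A[5, ] <- A[5, ] + 3                     # E only
  expect_warning(cr <- cluster_permutation_test(A, B, adj, n_perm = 199,
                                                seed = 2),
                 "disconnected")
  sizes <- vapply(cr$clusters, function(cl) length(cl$members), integer(1))
  e_cl <- which(vapply(cr$clusters, function(cl) "E" %in% cl$members,
                       logical(1)))
  expect_length(e_cl, 1)
  expect_equal(sizes[e_cl], 1L)
})
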