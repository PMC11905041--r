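#' Edge-wise group comparison of connectivity matrices with FDR correction
#'
#' For every unordered electrode pair, a two-sample permutation test (pooled
#' t statistic) compares the per-subject connectivity values between groups.
#' All edges share one permutation schedule (the same subject relabelings),
#' as required for valid simultaneous inference, and Benjamini-Hochberg FDR
#' is applied across edges within the band.
#'
#' @param matsA,matsB Lists of `connectivity_matrix` objects (one per
#'   subject), sharing band, metric and electrode labels; each group >= 2.
#' @param n_perm Number of permutations (default 50000; exhaustive
#'   enumeration is used when it is smaller).
#' @param seed RNG seed for the shared permutation schedule.
#' @param q FDR level (default 0.05).
#' @return An `edge_stats` data.frame: one row per edge with electrode
#'   labels, observed t, Cohen's d, direction (`"A>B"`/`"B>A"`), raw
#'   permutation `p` and BH-adjusted `p_adj`.
#' @export
edgewise_group_test <- function(matsA, matsB, n_perm = 50000, seed = NULL,
                                q = 0.05) {
  stopifnot(length(matsA) >= 2, length(matsB) >= 2)
  all_m <- c(matsA, matsB)
  b0 <- all_m[[1]]$band; l0 <- all_m[[1]]$labels
  for (m in all_m) {
    if (!isTRUE(all.equal(m$band, b0)) || !identical(m$labels, l0))
      stop("connectivity matrices differ in band or electrode labels")
  }
  nc <- length(l0)
  ut <- which(upper.tri(matrix(0, nc, nc)), arr.ind = TRUE)
  edge_vals <- function(m) m$values[ut]
  X <- vapply(all_m, edge_vals, numeric(nrow(ut)))   # edges x subjects
  X <- matrix(X, nrow = nrow(ut))
  nA <- length(matsA); n <- ncol(X)
  sched <- perm_schedule(n, nA, n_perm, seed)
  t_obs <- drop(perm_t_stats(X, matrix(c(rep(1, nA), rep(0, n - nA))), nA))
  tol <- 1e-8 * pmax(1, abs(t_obs))
  # chunk the schedule: the edge x permutation temporaries are memory-bound
  B <- ncol(sched$ind)
  hits <- numeric(nrow(X))
  for (j0 in seq(1, B, by = 512)) {
    jj <- j0:min(j0 + 511, B)
    t_perm <- perm_t_stats(X, sched$ind[, jj, drop = FALSE], nA)
    hits <- hits + rowSums(abs(t_perm) >= abs(t_obs) - tol)
  }
  p <- if (sched$exhaustive) hits / ncol(sched$ind)
       else (1 + hits) / (1 + ncol(sched$ind))
  d <- apply(X, 1, function(v) {
    xa <- v[seq_len(nA)]; xb <- v[-seq_len(nA)]
    sp2 <- ((nA - 1) * stats::var(xa) + (n - nA - 1) * stats::var(xb)) /
      (n - 2)
    if (sp2 == 0) {
      # degenerate edge (constant across subjects): no effect, not an error
      if (mean(xa) == mean(xb)) 0 else sign(mean(xa) - mean(xb)) * Inf
    } else (mean(xa) - mean(xb)) / sqrt(sp2)
  })
  adj <- fdr_bh(p, q)
  res <- data.frame(electrode_i = l0[ut[, 1]], electrode_j = l0[ut[, 2]],
                    t = t_obs, d = d,
                    direction = ifelse(t_obs >= 0, "A>B", "B>A"),
                    p = p, p_adj = adj$p_adj, significant = adj$reject,
                    stringsAsFactors = FALSE)
  attr(res, "band") <- b0
  attr(res, "metric") <- all_m[[1]]$metric
  attr(res, "n_perm") <- ncol(sched$ind)
  attr(res, "exhaustive") <- sched$exhaustive
  class(res) <- c("edge_stats", "data.frame")
  res
}

#' Cluster-based permutation test on electrode maps
#'
#' Electrode-wise pooled t statistics are thresholded at the two-sided t
#' critical value at `cluster_alpha`; supra-threshold electrodes of the same
#' sign that are neighbours in the adjacency graph form clusters, scored by
#' their mass (sum of |t|).  The familywise-corrected p of each observed
#' cluster is the fraction of relabelings whose *maximum* cluster mass
#' reaches it: `p = (1 + #{max_null >= mass}) / (1 + n_perm)`.
#'
#' @param mapsA,mapsB Electrode x subject matrices of per-subject scalar maps
#'   (e.g. relative band power), rows in montage order.
#' @param adjacency An `adjacency` over the same electrodes.
#' @param n_perm Number of permutations (default 50000).
#' @param seed RNG seed for the permutation schedule.
#' @param cluster_alpha Two-sided cluster-forming alpha (default 0.05).
#' @return A `cluster_result`: list with `clusters` (each: `members`
#'   labels, `mass`, `sign`, `p`), the electrode `t` vector, `t_threshold`,
#'   `n_perm`, `seed`.
#' @export
cluster_permutation_test <- function(mapsA, mapsB, adjacency, n_perm = 50000,
                                     seed = NULL, cluster_alpha = 0.05) {
  stopifnot(inherits(adjacency, "adjacency"))
  mapsA <- as.matrix(mapsA); mapsB <- as.matrix(mapsB)
  if (nrow(mapsA) != adjacency$n_nodes || nrow(mapsB) != adjacency$n_nodes)
    stop("maps must have one row per adjacency node")
  nA <- ncol(mapsA); nB <- ncol(mapsB)
  stopifnot(nA >= 2, nB >= 2)
  n <- nA + nB
  X <- cbind(mapsA, mapsB)
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 2)
  nb <- neighbor_list(adjacency)
  if (max(graph_components(nb, seq_len(adjacency$n_nodes))) > 1L)
    warning("adjacency graph is disconnected; clusters cannot span ",
            "components")
  cluster_masses <- function(tv) {
    out <- list()
    for (sgn in c(1, -1)) {
      nodes <- which(sgn * tv > thr)
      if (!length(nodes)) next
      comp <- graph_components(nb, nodes)
      for (cid in unique(comp)) {
        mem <- nodes[comp == cid]
        out[[length(out) + 1]] <- list(members = mem,
                                       mass = sum(abs(tv[mem])),
                                       sign = sgn)
      }
    }
    out
  }
  t_obs <- drop(perm_t_stats(X, matrix(c(rep(1, nA), rep(0, nB))), nA))
  obs <- cluster_masses(t_obs)
  sched <- perm_schedule(n, nA, n_perm, seed)
  t_perm <- perm_t_stats(X, sched$ind, nA)
  B <- ncol(sched$ind)
  max_null <- numeric(B)
  for (b in seq_len(B)) {
    cl <- cluster_masses(t_perm[, b])
    max_null[b] <- if (length(cl)) max(vapply(cl, `[[`, numeric(1), "mass"))
                   else 0
  }
  clusters <- lapply(obs, function(cl) {
    hits <- sum(max_null >= cl$mass - 1e-8)
    p <- if (sched$exhaustive) hits / B else (1 + hits) / (1 + B)
    list(members = adjacency$labels[cl$members], mass = cl$mass,
         sign = if (cl$sign > 0) "A>B" else "B>A", p = p)
  })
  ord <- order(vapply(clusters, `[[`, numeric(1), "p"))
  structure(list(clusters = clusters[ord], t = t_obs, t_threshold = thr,
                 labels = adjacency$labels, n_perm = B, seed = seed,
                 cluster_alpha = cluster_alpha,
                 exhaustive = sched$exhaustive),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), |t| threshold %.2f, %d perms\n",
              length(x$clusters), x$t_threshold, x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  %s  mass %.1f  p = %.4g  [%s]\n", cl$sign, cl$mass, cl$p,
                paste(cl$members, collapse = " ")))
  invisible(x)
}
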