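#' Pooled two-sample t statistic from summary statistics
#'
#' `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))` with pooled variance
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.  Useful for
#' checking published demographic tables where only means and SDs are
#' printed.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return The t statistic (numeric scalar).
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) return(0)
    stop("zero pooled variance with unequal means: t undefined")
  }
  (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
}

#' Cohen's d with pooled standard deviation
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return Signed effect size `(mean(x) - mean(y)) / s_p`.
#' @export
cohens_d <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) stop("zero pooled standard deviation: d undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

# Internal: permutation schedule over n subjects, nA in group A.
# Exhaustive when the number of distinct relabelings fits in n_perm;
# otherwise n_perm uniform random relabelings.  Returns an n x B 0/1
# indicator matrix plus the exhaustiveness flag.
perm_schedule <- function(n, nA, n_perm, seed = NULL) {
  n_distinct <- choose(n, nA)
  if (is.finite(n_distinct) && n_distinct <= n_perm) {
    combs <- utils::combn(n, nA)
    ind <- matrix(0, n, ncol(combs))
    ind[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = nA))] <- 1
    list(ind = ind, exhaustive = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ind <- vapply(seq_len(n_perm), function(b) {
      v <- numeric(n); v[sample.int(n, nA)] <- 1; v
    }, numeric(n))
    list(ind = ind, exhaustive = FALSE)
  }
}

# Internal: pooled two-sample t for each row of X (features x subjects)
# under each relabeling column of `ind`.  Zero-variance relabelings give
# t = 0 when the mean difference is 0, +/-Inf otherwise.
perm_t_stats <- function(X, ind, nA) {
  X <- matrix(X, ncol = nrow(ind))
  n <- ncol(X); nB <- n - nA
  SA <- X %*% ind
  SSA <- (X^2) %*% ind
  tot <- rowSums(X); totsq <- rowSums(X^2)
  mA <- SA / nA
  mB <- (tot - SA) / nB
  ssA <- SSA - SA^2 / nA
  ssB <- (totsq - SSA) - (tot - SA)^2 / nB
  sp2 <- pmax((ssA + ssB) / (n - 2), 0)   # clamp catastrophic cancellation
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tmat <- (mA - mB) / se                  # x/0 -> +/-Inf, 0/0 -> NaN
  tmat[is.nan(tmat)] <- 0
  tmat
}

#' Two-sample permutation test on scalar observations
#'
#' The test statistic is the pooled two-sample t; the null distribution is
#' its value under random relabelings that preserve group sizes.  When the
#' number of distinct relabelings is at most `n_perm` the test enumerates all
#' of them exactly (and the p-value denominator is the number of
#' relabelings); otherwise `n_perm` Monte-Carlo relabelings are drawn and
#' `p = (1 + #{|t_perm| >= |t_obs|}) / (1 + n_perm)`, never exactly zero.
#'
#' @param a,b Numeric vectors of per-subject values (each length >= 2).
#' @param n_perm Number of permutations (default 50000).
#' @param seed Optional RNG seed for the relabelings.
#' @param two_sided Two-sided test (default) or one-sided (`a > b`).
#' @return List with `p`, `t_obs`, `n_perm_used`, `exhaustive`.
#' @export
permutation_test <- function(a, b, n_perm = 50000, seed = NULL,
                             two_sided = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2, n_perm >= 1)
  x <- c(a, b)
  if (max(x) == min(x))
    return(list(p = 1, t_obs = 0, n_perm_used = 0L, exhaustive = TRUE))
  n <- length(x); nA <- length(a)
  sched <- perm_schedule(n, nA, n_perm, seed)
  X <- matrix(x, 1)
  t_perm <- drop(perm_t_stats(X, sched$ind, nA))
  t_obs <- drop(perm_t_stats(X, matrix(c(rep(1, nA), rep(0, n - nA))), nA))
  tol <- 1e-8 * max(1, abs(t_obs))
  stat_p <- if (two_sided) abs(t_perm) else t_perm
  stat_o <- if (two_sided) abs(t_obs) else t_obs
  hits <- sum(stat_p >= stat_o - tol)
  p <- if (sched$exhaustive) hits / ncol(sched$ind)
       else (1 + hits) / (1 + ncol(sched$ind))
  list(p = p, t_obs = t_obs, n_perm_used = ncol(sched$ind),
       exhaustive = sched$exhaustive)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")`) and the
#' rejection mask at level `q`.
#'
#' @param pvals Raw p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `p_adj` and logical `reject`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0)
    return(list(p_adj = numeric(0), reject = logical(0)))
  stopifnot(all(pvals > 0 & pvals <= 1))
  p_adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= q)
}

#' Rank correlations
#'
#' `spearman_rho()` is the Pearson correlation of mid-ranks.
#' `kendall_tau_b()` counts concordant/discordant pairs with the standard
#' tie correction in both margins.
#'
#' @param x,y Equal-length numeric vectors, length >= 3; ties allowed.
#' @return The correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance: correlation undefined")
  stats::cor(rx, ry)
}

#' @rdname spearman_rho
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  if (max(x) == min(x) || max(y) == min(y))
    stop("zero rank variance: correlation undefined")
  dx <- sign(outer(x, x, `-`)); dy <- sign(outer(y, y, `-`))
  ut <- upper.tri(dx)
  conc_disc <- sum(dx[ut] * dy[ut])
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    tt <- table(v); sum(tt * (tt - 1) / 2)
  }
  n1 <- tie_term(x); n2 <- tie_term(y)
  conc_disc / sqrt((n0 - n1) * (n0 - n2))
}

#' Interquartile-range outlier detection
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation (R's default quantile type 7).
#'
#' @param values Numeric vector of length >= 4.
#' @param k Fence multiplier (default 1.5).
#' @return Logical mask, `TRUE` for outliers.
#' @export
iqr_outliers <- function(values, k = 1.5) {
  stopifnot(length(values) >= 4)
  qs <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  values < qs[1] - k * iqr | values > qs[2] + k * iqr
}
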