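# Nonparametric permutation machinery: paired, independent, sign-flip and
# time-resolved cluster permutation tests. All tests are two-sided,
# reproducible under a seed, and switch to exact enumeration when the
# permutation space is small enough.

perm_result <- function(statistic, p_value, n_permutations, exact, seed) {
  structure(
    list(statistic = statistic, p_value = p_value,
         n_permutations = n_permutations, exact = exact, seed = seed,
         tails = "two_sided"),
    class = "kinestim_perm")
}

#' @export
print.kinestim_perm <- function(x, ...) {
  cat(sprintf("Two-sided permutation test: statistic = %.4g, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p_value,
              if (x$exact) "exact enumeration" else "Monte Carlo",
              x$n_permutations))
  invisible(x)
}

# Shared sign-flip engine: statistic = mean(d); null by random (or fully
# enumerated) sign flips. Exact enumeration is used when 2^n <= n_perm and
# then yields p = b / 2^n; Monte Carlo uses the add-one correction
# p = (b + 1) / (n_perm + 1).
signflip_engine <- function(d, n_perm, seed) {
  n <- length(d)
  obs <- mean(d)
  tol <- sqrt(.Machine$double.eps) * max(abs(d), 1)
  if (all(d == 0)) {
    return(perm_result(0, 1, n_perm, TRUE, seed))
  }
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- as.vector(signs %*% d) / n
    p <- mean(abs(null) >= abs(obs) - tol)
    return(perm_result(obs, p, 2L^n, TRUE, seed))
  }
  with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    null <- as.vector(S %*% d) / n
    p <- (sum(abs(null) >= abs(obs) - tol) + 1) / (n_perm + 1)
    perm_result(obs, p, n_perm, FALSE, seed)
  })
}

#' Paired-sample permutation test
#'
#' Two-sided test of the mean within-pair difference. The null distribution
#' is built by exchanging labels within pairs, i.e. sign-flipping the
#' differences; enumeration is exact when `2^n <= n_perm`, otherwise Monte
#' Carlo with the add-one correction `p = (b + 1) / (n_perm + 1)`.
#'
#' @param a,b Paired per-subject values of equal length.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return A `kinestim_perm` result.
#' @export
paired_permutation_test <- function(a, b, n_perm = 1e5, seed = NULL) {
  if (length(a) != length(b)) {
    abort_invalid("`a` and `b` must have equal length (paired by subject)")
  }
  if (length(a) < 2L) abort_invalid("need at least 2 pairs")
  signflip_engine(a - b, as.integer(n_perm), seed)
}

#' Sign-flip permutation test against zero
#'
#' Two-sided test of `mean(x) = 0` with random sign flips; all-zero input
#' yields p = 1 by convention.
#'
#' @param x Per-subject values.
#' @inheritParams paired_permutation_test
#' @return A `kinestim_perm` result.
#' @export
signflip_test <- function(x, n_perm = 1e5, seed = NULL) {
  if (length(x) < 2L) abort_invalid("need at least 2 values")
  signflip_engine(x, as.integer(n_perm), seed)
}

#' Independent-sample permutation test
#'
#' Two-sided test of the difference in group means; the null shuffles group
#' assignment over the pooled values. Enumeration is exact when
#' `choose(n, n_a) <= n_perm`.
#'
#' @param a,b The two groups.
#' @inheritParams paired_permutation_test
#' @return A `kinestim_perm` result.
#' @export
independent_permutation_test <- function(a, b, n_perm = 1e5, seed = NULL) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort_invalid("both groups need at least 2 non-missing values")
  }
  n_perm <- as.integer(n_perm)
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  pooled <- c(a, b)
  tot <- sum(pooled)
  obs <- mean(a) - mean(b)
  tol <- sqrt(.Machine$double.eps) * max(abs(pooled), 1)
  if (choose(n, na) <= n_perm) {
    idx <- utils::combn(n, na)
    sa <- colSums(matrix(pooled[idx], nrow = na))
    null <- sa / na - (tot - sa) / nb
    p <- mean(abs(null) >= abs(obs) - tol)
    return(perm_result(obs, p, ncol(idx), TRUE, seed))
  }
  with_seed(seed, {
    null <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      sa <- sum(pooled[sample.int(n, na)])
      null[r] <- sa / na - (tot - sa) / nb
    }
    p <- (sum(abs(null) >= abs(obs) - tol) + 1) / (n_perm + 1)
    perm_result(obs, p, n_perm, FALSE, seed)
  })
}

# Vectorised Welch t statistics and degrees of freedom over the columns of
# two trial-by-time matrices.
welch_t_cols <- function(a, b) {
  na <- nrow(a)
  nb <- nrow(b)
  ma <- colMeans(a)
  mb <- colMeans(b)
  va <- (colMeans(a^2) - ma^2) * na / (na - 1)
  vb <- (colMeans(b^2) - mb^2) * nb / (nb - 1)
  sa <- va / na
  sb <- vb / nb
  se2 <- sa + sb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  list(t = t, df = df)
}

# Maximal contiguous supra-threshold runs; adjacency follows time_index so
# clusters cannot bridge removed time points.
find_clusters <- function(supra, tvals, time_index) {
  if (!any(supra)) {
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      mass = numeric(0)))
  }
  brk <- c(TRUE, diff(time_index) != 1L)
  grp <- cumsum(brk | c(TRUE, !supra[-length(supra)]))
  grp[!supra] <- NA
  ids <- unique(grp[!is.na(grp)])
  do.call(rbind, lapply(ids, function(g) {
    jj <- which(!is.na(grp) & grp == g)
    data.frame(start_index = time_index[min(jj)],
               end_index = time_index[max(jj)],
               mass = sum(abs(tvals[jj])))
  }))
}

#' Cluster-based permutation test over a time axis
#'
#' Point-wise Welch t statistics between two groups of time series are
#' thresholded at the two-sided alpha quantile of the t distribution
#' (cluster-forming threshold); cluster mass is the sum of |t| within each
#' maximal contiguous supra-threshold run. The null distribution is the
#' maximal cluster mass over random relabellings of the trials, giving
#' family-wise-error-controlled cluster p values. Non-adjacent time indices
#' (e.g. points removed by the masked-epoch rule) break cluster contiguity.
#'
#' @param group_a,group_b Trials-by-time matrices on aligned time axes.
#' @param n_perm Number of label permutations.
#' @param alpha Two-sided alpha of the cluster-forming threshold.
#' @param seed Optional integer seed.
#' @param time_index Integer positions of the columns on the original time
#'   axis (defaults to `1:ncol`); used for adjacency and reporting.
#' @return A list of class `kinestim_clusters` with `clusters` (start/end
#'   index, mass, p_value), `t`, `df`, `threshold`, `n_permutations`,
#'   `alpha` and the null maxima.
#' @export
cluster_permutation_test <- function(group_a, group_b, n_perm = 1000,
                                     alpha = 0.05, seed = NULL,
                                     time_index = NULL) {
  if (nrow(group_a) < 2L || nrow(group_b) < 2L) {
    abort_invalid("both groups need at least 2 trials")
  }
  if (ncol(group_a) != ncol(group_b)) {
    abort_invalid("time axes of the two groups are not aligned")
  }
  if (is.null(time_index)) time_index <- seq_len(ncol(group_a))
  na <- nrow(group_a)
  n <- na + nrow(group_b)
  X <- rbind(group_a, group_b)

  wt <- welch_t_cols(group_a, group_b)
  thr <- stats::qt(1 - alpha / 2, wt$df)
  clusters <- find_clusters(abs(wt$t) > thr, wt$t, time_index)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      idx <- sample.int(n, na)
      wtp <- welch_t_cols(X[idx, , drop = FALSE], X[-idx, , drop = FALSE])
      thrp <- stats::qt(1 - alpha / 2, wtp$df)
      cl <- find_clusters(abs(wtp$t) > thrp, wtp$t, time_index)
      if (nrow(cl)) max(cl$mass) else 0
    }, numeric(1))
  })
  clusters$p_value <- if (nrow(clusters)) {
    vapply(clusters$mass, function(m) {
      (sum(null_max >= m) + 1) / (n_perm + 1)
    }, numeric(1))
  } else numeric(0)
  structure(
    list(clusters = clusters, t = wt$t, df = wt$df, threshold = thr,
         n_permutations = n_perm, alpha = alpha, null_max = null_max,
         time_index = time_index),
    class = "kinestim_clusters")
}
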