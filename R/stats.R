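## Exact small-sample Wilcoxon tests and the leave-one-out (LOO) p-value
## range. The exact two-sided p-values are computed by complete enumeration
## of the permutation distribution of the observed (mid-)ranks, implemented
## as a subset-sum counting recursion, so ties are permitted.

## Count, for every achievable (size, sum) pair, the number of subsets of
## the doubled ranks R with that size and sum. Returns a (m+1) x (S+1)
## matrix of counts, f[k+1, s+1] = #subsets of size k summing to s.
.subsetSumCounts <- function(R, m) {
  S <- sum(R)
  f <- matrix(0, nrow = m + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  for (r in R) {
    kmax <- min(m, nrow(f) - 1L)
    for (k in kmax:1L) {
      idx <- seq_len(S + 1L - r)
      f[k + 1L, idx + r] <- f[k + 1L, idx + r] + f[k, idx]
    }
  }
  f
}

## Midranks of a combined sample.
.midranks <- function(v) rank(v, ties.method = "average")

#' Exact unpaired Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test comparing two independent
#' groups. For group sizes up to \code{exactMax} the p-value is exact: the
#' permutation distribution of the rank-sum statistic over all
#' choose(n+m, n) group assignments of the observed (mid-)ranks is fully
#' enumerated, so ties are handled exactly. Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (>= 3 values each recommended).
#' @param exactMax largest per-group size for exact enumeration.
#' @return list: \code{statistic} (rank sum of \code{x}), \code{p_value},
#'   \code{method} ("exact" or "normal").
#' @export
wilcoxonRankSum <- function(x, y, exactMax = 10L) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1L, m >= 1L)
  v <- c(x, y)
  if (length(unique(v)) == 1L)
    warning("all observations tied; p = 1")
  r <- .midranks(v)
  W <- sum(r[seq_len(n)])
  N <- n + m
  if (max(n, m) <= exactMax) {
    R2 <- as.integer(round(2 * r))
    f <- .subsetSumCounts(R2, n)
    counts <- f[n + 1L, ]
    sums <- seq_along(counts) - 1L
    mu2 <- n * (N + 1)                       # doubled mean rank sum
    dev <- abs(2 * W - mu2)
    p <- sum(counts[abs(sums - mu2) >= dev - 1e-9]) / sum(counts)
    list(statistic = W, p_value = min(p, 1), method = "exact")
  } else {
    mu <- n * (N + 1) / 2
    ties <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) return(list(statistic = W, p_value = 1, method = "normal"))
    z <- (abs(W - mu) - 0.5) / sqrt(sig2)
    list(statistic = W, p_value = min(1, 2 * stats::pnorm(-max(z, 0))),
         method = "normal")
  }
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (with a warning). For up to \code{exactMax} non-zero pairs the
#' p-value is exact over all 2^n sign assignments of the observed
#' (mid-)ranks of |d|; larger samples use the tie-corrected normal
#' approximation.
#'
#' @param x numeric vector of first measurements, or of differences when
#'   \code{y} is \code{NULL}.
#' @param y optional numeric vector paired with \code{x}.
#' @param exactMax largest number of non-zero pairs for exact enumeration.
#' @return list: \code{statistic} (positive-rank sum V), \code{p_value},
#'   \code{method}.
#' @export
wilcoxonSignedRank <- function(x, y = NULL, exactMax = 10L) {
  d <- if (is.null(y)) x else x - y
  if (any(d == 0)) {
    warning("zero differences dropped")
    d <- d[d != 0]
  }
  n <- length(d)
  if (n == 0L) {
    warning("all differences zero; p = 1")
    return(list(statistic = 0, p_value = 1, method = "exact"))
  }
  r <- .midranks(abs(d))
  V <- sum(r[d > 0])
  if (n <= exactMax) {
    R2 <- as.integer(round(2 * r))
    f <- .subsetSumCounts(R2, n)
    counts <- colSums(f)                     # subsets of any size
    sums <- seq_along(counts) - 1L
    mu2 <- sum(R2) / 2
    dev <- abs(2 * V - mu2)
    p <- sum(counts[abs(sums - mu2) >= dev - 1e-9]) / 2^n
    list(statistic = V, p_value = min(p, 1), method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sig2 <= 0) return(list(statistic = V, p_value = 1, method = "normal"))
    z <- (abs(V - mu) - 0.5) / sqrt(sig2)
    list(statistic = V, p_value = min(1, 2 * stats::pnorm(-max(z, 0))),
         method = "normal")
  }
}

#' Leave-one-out p-value range
#'
#' Small-sample robustness check: the chosen test is recomputed with one
#' subject omitted at a time (every subject of both groups for the unpaired
#' test; every pair for the paired test) and the minimum and maximum of the
#' resulting p-values are reported. Omissions producing a degenerate test
#' are skipped with a warning.
#'
#' @param x,y the two groups (unpaired) or paired vectors.
#' @param test \code{"unpaired"} (rank-sum) or \code{"paired"} (signed-rank).
#' @param exactMax passed to the underlying test.
#' @return list: \code{p_min}, \code{p_max}, \code{p_values} (named by the
#'   omitted index).
#' @export
leaveOneOutPvalues <- function(x, y, test = c("unpaired", "paired"),
                               exactMax = 10L) {
  test <- match.arg(test)
  run <- function(xx, yy) {
    if (test == "unpaired") wilcoxonRankSum(xx, yy, exactMax)$p_value
    else wilcoxonSignedRank(xx, yy, exactMax)$p_value
  }
  ps <- c()
  if (test == "unpaired") {
    for (i in seq_along(x)) {
      if (length(x) - 1L < 1L) { warning("degenerate omission skipped"); next }
      ps[paste0("x", i)] <- suppressWarnings(run(x[-i], y))
    }
    for (j in seq_along(y)) {
      if (length(y) - 1L < 1L) { warning("degenerate omission skipped"); next }
      ps[paste0("y", j)] <- suppressWarnings(run(x, y[-j]))
    }
  } else {
    stopifnot(length(x) == length(y))
    for (i in seq_along(x)) {
      if (length(x) - 1L < 1L) { warning("degenerate omission skipped"); next }
      ps[paste0("pair", i)] <- suppressWarnings(run(x[-i], y[-i]))
    }
  }
  list(p_min = min(ps), p_max = max(ps), p_values = ps)
}
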