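# Small-sample exact rank tests.
#
# Base R's wilcox.test() switches to a normal approximation as soon as the
# data contain ties or zeros; the pairwise chip comparisons and the qPCR
# group tests here involve exactly such small, possibly tied samples, so the
# exact null distributions are computed directly (signed-rank: convolution
# over per-rank sign assignments; rank-sum: subset dynamic programme over
# the tied midranks).  Tie-free cases go through psignrank()/pwilcox().

# distribution of the positive-rank sum over all 2^n sign assignments of
# (possibly tied, possibly non-integer) ranks r; returns counts indexed by
# doubled statistic 0..2*sum(r)
signed_rank_null_counts <- function(r) {
  r2 <- as.integer(round(2 * r))  # midranks are multiples of 1/2
  counts <- numeric(sum(r2) + 1)
  counts[1] <- 1
  for (v in r2) {
    shifted <- c(rep(0, v), counts[seq_len(length(counts) - v)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test against zero
#'
#' Two-sided one-sample signed-rank test of the differences `d` against a
#' zero location.  Zeros are discarded; absolute values are midranked.  The
#' p-value is exact — via the closed-form null distribution when the
#' absolute values are tie-free, otherwise by convolving the tied-rank sign
#' distribution for up to 20 non-zero differences — and falls back to the
#' tie-corrected normal approximation beyond that.
#'
#' @param d numeric vector of differences (e.g. per-probe log ratios).
#' @return list with `statistic` (positive-rank sum W) and `p.value`.
#' @export
wilcoxon_signed_rank <- function(d) {
  if (length(d) == 0) stop("no differences supplied", call. = FALSE)
  if (anyNA(d)) stop("missing values are not allowed", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p.value = 1))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties) {
    p <- 2 * min(psignrank(w, n), psignrank(n * (n + 1) / 2 - w, n))
  } else if (n <= 20) {
    counts <- signed_rank_null_counts(r)
    w2 <- as.integer(round(2 * w))
    lower <- sum(counts[seq_len(w2 + 1)])
    upper <- sum(counts[seq(w2 + 1, length(counts))])
    p <- 2 * min(lower, upper) / sum(counts)
  } else {
    tie_sizes <- table(r)
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    p <- 2 * pnorm(-abs(w - mu) / sqrt(sigma2))
  }
  list(statistic = w, p.value = min(1, p))
}

# distribution of the group-a rank sum over all C(n, n_a) subsets of the
# pooled (possibly tied) ranks; dynamic programme over items with states
# (subset size, doubled rank sum)
rank_sum_null_counts <- function(r, n_a) {
  r2 <- as.integer(round(2 * r))
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n_a)])
  # counts[k + 1, s + 1] = number of size-k subsets with doubled sum s
  counts <- matrix(0, nrow = n_a + 1, ncol = smax + 1)
  counts[1, 1] <- 1
  for (v in r2) {
    for (k in rev(seq_len(n_a))) {
      shifted <- c(rep(0, v), counts[k, seq_len(smax + 1 - v)])
      counts[k + 1, ] <- counts[k + 1, ] + shifted
    }
  }
  counts[n_a + 1, ]
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test between two independent groups.  The reported U
#' is the smaller of the two group statistics.  The p-value is exact — via
#' `pwilcox()` when there are no ties, otherwise by enumerating the
#' permutation distribution of the rank sum over tied midranks — whenever
#' the smaller group has at most 10 observations and the pooled sample at
#' most 25; larger samples use the tie-corrected normal approximation.
#'
#' @param group_a,group_b numeric vectors of observations.
#' @return list with `U` (min of the two group statistics), `p.value`,
#'   `n_a`, `n_b` and `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(5, 6, 7), c(1, 2, 3))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(group_a) || anyNA(group_b))
    stop("missing values are not allowed", call. = FALSE)
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  ra <- sum(r[seq_len(n_a)])
  u_a <- ra - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  u <- min(u_a, u_b)
  ties <- anyDuplicated(pooled) > 0
  exact_ok <- min(n_a, n_b) <= 10 && (n_a + n_b) <= 25
  if (exact_ok && !ties) {
    p <- min(1, 2 * pwilcox(u, n_a, n_b))
    method <- "exact"
  } else if (exact_ok) {
    counts <- rank_sum_null_counts(r, n_a)
    ra2 <- as.integer(round(2 * ra))
    idx <- seq_along(counts) - 1          # doubled rank sums present
    lower <- sum(counts[idx <= ra2])
    upper <- sum(counts[idx >= ra2])
    p <- min(1, 2 * min(lower, upper) / sum(counts))
    method <- "exact"
  } else {
    tie_sizes <- table(r)
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    sigma2 <- n_a * n_b / 12 *
      ((n + 1) - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
    p <- 2 * pnorm(-abs(u_a - mu) / sqrt(sigma2))
    p <- min(1, p)
    method <- "normal"
  }
  list(U = u, p.value = p, n_a = n_a, n_b = n_b, method = method)
}
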