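# Independent brute-force oracles used to validate the statistical kernels
# and the pairwise screen.  Deliberately written from first principles
# (explicit midranks, explicit sums, exhaustive enumeration) rather than
# through the package's own code paths or base R's rank()/cor().

# midranks computed by counting, not via rank()
oracle_midranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Spearman r as the explicit Pearson product-moment formula on midranks
oracle_spearman_r <- function(x, y) {
  rx <- oracle_midranks(x)
  ry <- oracle_midranks(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- oracle_midranks(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

# exact two-sided rank-sum p by enumerating all C(n, n_a) group labelings
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- oracle_midranks(pooled)
  ra_obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  ra_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p <- 2 * min(mean(ra_all <= ra_obs), mean(ra_all >= ra_obs))
  u_a <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  list(U = min(u_a, n_a * length(b) - u_a), p = min(1, p))
}

# brute-force pairwise screen: per gene, loop over every AF x NP chip
# pair, recompute the median probe log ratio and the exact enumeration
# signed-rank p, count qualifying calls
oracle_screen <- function(em, fc_threshold = 2, consistency = 0.8,
                          alpha = 0.05) {
  af <- which(em$group == "AF")
  np <- which(em$group == "NP")
  out <- list()
  for (g in seq_along(em$gene_ids)) {
    n_inc <- 0L; n_dec <- 0L; n_pairs <- 0L
    for (i in af) for (j in np) {
      lr <- log2(em$probe_signals[g, i, ] / em$probe_signals[g, j, ])
      slr <- sort(lr)[c(ceiling(length(lr) / 2),
                        floor(length(lr) / 2) + 1)]
      slr <- mean(slr)
      p <- oracle_signed_rank_p(lr)
      fc <- 2^slr
      n_pairs <- n_pairs + 1L
      if (fc > fc_threshold && p < alpha) n_inc <- n_inc + 1L
      if (fc < 1 / fc_threshold && p < alpha) n_dec <- n_dec + 1L
    }
    dir <- if (n_inc / n_pairs >= consistency) "AF_up"
           else if (n_dec / n_pairs >= consistency) "NP_up" else NA
    if (!is.na(dir))
      out[[length(out) + 1L]] <- data.frame(gene_id = em$gene_ids[g],
                                            direction = dir,
                                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(gene_id = character(), direction = character())
}

table3_records <- function() read_score_sheet(discqc_fixture("table3.tsv"))
table5_calls <- function() read_call_table(discqc_fixture("table5.tsv"))
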