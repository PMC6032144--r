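# small helper: expression matrix with constant probe signals per
# (gene, chip) cell, 11 probes per set
constant_probe_matrix <- function(signal, group, floor = 100) {
  p <- 11
  probes <- array(rep(signal, p), dim = c(dim(signal), p),
                  dimnames = list(rownames(signal), colnames(signal), NULL))
  expression_matrix(signal = signal, group = group, probe_signals = probes,
                    detection_floor = floor)
}

test_that("detection calls use an inclusive floor", {
  expect_true(detection_call(800, 100))
  expect_false(detection_call(99.9, 100))
  expect_true(detection_call(100, 100))
  expect_error(detection_call(0, 100), "positive")
})

test_that("pairwise comparison recovers constant ratios and flags no change", {
  res <- pairwise_compare(rep(800, 11), rep(100, 11))
  expect_equal(res$slr, 3)
  expect_equal(res$fc, 8)
  expect_equal(res$change_call, "increased")
  same <- pairwise_compare(rep(5, 11), rep(5, 11))
  expect_equal(same$slr, 0)
  expect_equal(same$fc, 1)
  expect_equal(same$change_call, "no_change")
  expect_equal(same$p, 1)
  expect_error(pairwise_compare(1:4, 1:4), "at least 5")
  expect_error(pairwise_compare(c(1, 2, 3, 4, 0), 1:5), "positive")
})

test_that("pairwise p equals exhaustive enumeration for mixed-sign probes", {
  set.seed(5)
  for (i in 1:10) {
    af <- rlnorm(6, 5, 0.5)
    np <- rlnorm(6, 5, 0.5)
    res <- pairwise_compare(af, np)
    expect_equal(res$p, oracle_signed_rank_p(log2(af / np)),
                 tolerance = 1e-12)
  }
})

test_that("a noiseless planted gene is fully consistent across all pairs", {
  sig <- rbind(G1 = c(rep(800, 11), rep(100, 9)),
               FLAT = rep(500, 20))
  colnames(sig) <- paste0("c", 1:20)
  em <- constant_probe_matrix(sig, rep(c("AF", "NP"), c(11, 9)))
  degs <- screen_degs(em)
  expect_equal(degs$gene_id, "G1")
  expect_equal(degs$direction, "AF_up")
  expect_equal(degs$fc_mean, 8)
  expect_equal(degs$fc_sd, 0)
  expect_equal(degs$change_pct, 100)
  expect_equal(degs$detection_pct_np, 100)
})

test_that("NP-up genes are reported on the NP/AF scale", {
  sig <- rbind(G1 = c(rep(100, 3), rep(400, 3)))
  colnames(sig) <- paste0("c", 1:6)
  em <- constant_probe_matrix(sig, rep(c("AF", "NP"), each = 3))
  degs <- screen_degs(em)
  expect_equal(degs$direction, "NP_up")
  expect_equal(degs$fc_mean, 4)  # FC > 1 on the up-regulated scale
})

test_that("screen requires two chips per group", {
  sig <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("c", 1:4)))
  em <- constant_probe_matrix(sig, c("AF", "NP", "NP", "NP"))
  expect_error(screen_degs(em), "at least 2 chips")
})

test_that("noiseless screen equals the brute-force pair-counting oracle", {
  cfg <- sim_config(seed = 3, n_genes = 120, n_af = 5, n_np = 5,
                    n_af_up = 10, n_np_up = 5, noise_sigma = 0)
  sim <- simulate_expression(cfg)
  degs <- screen_degs(sim$matrix, consistency = 1.0)
  orc <- oracle_screen(sim$matrix, consistency = 1.0)
  expect_equal(degs$gene_id[order(degs$gene_id)],
               orc$gene_id[order(orc$gene_id)])
  m <- merge(degs, orc, by = "gene_id")
  expect_equal(m$direction.x, m$direction.y)
  # and the planted truth is recovered exactly, with no false positive
  planted <- sim$truth[sim$truth$label != "null", ]
  expect_setequal(degs$gene_id, planted$gene_id)
})

test_that("group-label swap maps AF-up to NP-up with identical fold-changes", {
  cfg <- sim_config(seed = 9, n_genes = 80, n_af = 4, n_np = 4,
                    n_af_up = 8, n_np_up = 4)
  sim <- simulate_expression(cfg)
  em <- sim$matrix
  em_sw <- expression_matrix(signal = em$signal,
                             group = ifelse(em$group == "AF", "NP", "AF"),
                             probe_signals = em$probe_signals,
                             detection = em$detection)
  a <- screen_degs(em)
  b <- screen_degs(em_sw)
  expect_setequal(a$gene_id, b$gene_id)
  m <- merge(a, b, by = "gene_id")
  expect_true(all(m$direction.x != m$direction.y))
  expect_equal(m$fc_mean.x, m$fc_mean.y)
})

test_that("every retained gene meets the consistency threshold", {
  cfg <- sim_config(seed = 21, n_genes = 300, n_af = 6, n_np = 5,
                    n_af_up = 15, n_np_up = 8)
  degs <- screen_degs(simulate_expression(cfg)$matrix, consistency = 0.8)
  expect_true(all(degs$change_pct >= 80))
  expect_true(all(degs$fc_mean > 0))
})

test_that("candidate filters implement the two-tier selection", {
  degs <- data.frame(
    gene_id = c("A1", "A2", "A3", "N1", "N2", "N3"),
    direction = c("AF_up", "AF_up", "AF_up", "NP_up", "NP_up", "NP_up"),
    fc_mean = c(30, 30, 20, 3.5, 3.5, 2.5),
    fc_sd = 1, change_pct = 100,
    detection_pct_af = 100, detection_pct_np = c(0, 20, 0, 100, 90, 100),
    p_median = c(0.01, 0.01, 0.01, 0.001, 0.001, 0.001),
    signal_mean_af = 1000, signal_mean_np = c(10, 50, 10, 500, 500, 40),
    stringsAsFactors = FALSE)
  class(degs) <- c("deg_records", "data.frame")
  sel <- select_candidates(degs, candidate_criteria(), noise_floor = 100)
  # A1 passes; A2 fails NP detection% = 0; A3 fails FC >= 24.4
  expect_equal(sel$af_candidates$gene_id, "A1")
  # N1 passes; N2 fails detection% >= 100; N3 fails FC and signal floor
  expect_equal(sel$np_candidates$gene_id, "N1")
  # exclusion list removes a would-be candidate
  sel2 <- select_candidates(degs,
    candidate_criteria(exclusion_list = "A1"), noise_floor = 100)
  expect_equal(nrow(sel2$af_candidates), 0)
  expect_error(select_candidates(degs[0, ], candidate_criteria(), 100),
               "no screened genes")
})

test_that("top-k depth cuts the ranked list before filtering", {
  degs <- data.frame(
    gene_id = sprintf("G%02d", 1:30), direction = "AF_up",
    fc_mean = seq(100, 42, length.out = 30), fc_sd = 1, change_pct = 100,
    detection_pct_af = 100, detection_pct_np = 0, p_median = 0.01,
    signal_mean_af = 1000, signal_mean_np = 10, stringsAsFactors = FALSE)
  class(degs) <- c("deg_records", "data.frame")
  sel <- select_candidates(degs, candidate_criteria(top_k_af = 25), 100)
  expect_equal(nrow(sel$af_candidates), 25)
  expect_equal(sel$af_candidates$gene_id[1], "G01")
})
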