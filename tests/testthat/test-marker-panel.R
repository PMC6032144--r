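test_that("ranges are the min-max over clear samples, with >= 2 values required", {
  panel <- marker_panel(af_markers = c("M1", "M2"), np_markers = c("M3", "M4"))
  af <- rbind(M1 = c(0.2, 0.5, 0.9), M2 = c(1, 2, NA))
  np <- rbind(M3 = c(0.1, 0.4, 0.2), M4 = c(5, 3, 4))
  fitted <- fit_ranges(panel, af, np)
  r <- fitted$ranges
  expect_equal(r[r$marker == "M1", c("low", "high")],
               data.frame(low = 0.2, high = 0.9), ignore_attr = TRUE)
  expect_equal(r[r$marker == "M2", c("low", "high")],
               data.frame(low = 1, high = 2), ignore_attr = TRUE)
  af_bad <- rbind(M1 = c(0.2, NA, NA), M2 = c(1, 2, 3))
  expect_error(fit_ranges(panel, af_bad, np), "marker M1 has 1 value")
})

test_that("marker calls respect inclusive boundaries and the no-expression rule", {
  expect_equal(call_marker(0.1, 0.1, 1.0), "+")   # low boundary inclusive
  expect_equal(call_marker(1.0, 0.1, 1.0), "+")   # high boundary inclusive
  expect_equal(call_marker(2.0, 0.1, 1.0), "++")
  expect_equal(call_marker(0.05, 0.1, 1.0), "-")
  expect_equal(call_marker(0, 0.1, 1.0), "-")     # no expression
  expect_equal(call_marker(NA, 0.1, 1.0), NA_character_)
  expect_error(call_marker(-1, 0.1, 1.0), "non-negative")
})

test_that("match percentage counts positives over available calls", {
  expect_equal(match_percent(c("+", "-", "++", "+", "+", "+")), 83)
  expect_equal(match_percent(c(NA, "+", "-", "-", "+", "-")), 40)
  expect_equal(match_percent(c("-", "-", "-", "-", "+", "-")), 17)
  expect_equal(match_percent(rep(NA_character_, 5)), NA_real_)
  expect_error(match_percent(c("+", "+++")), "unknown call token")
})

test_that("match percentage ignores marker order and added NA calls", {
  calls <- c("+", "-", "++", "+", "+", "+")
  expect_equal(match_percent(sample(calls)), match_percent(calls))
  expect_equal(match_percent(c(calls, NA)), match_percent(calls))
})

test_that("profile verdicts follow the all-AF-positive / no-AF-plus-NP rule", {
  rule <- panel_rule()
  af14 <- classify_profile(c("++", "+", NA, "+", "++"),
                           c(NA, "-", "-", "-", "-", "-"), rule)
  expect_equal(af14$verdict, "AF")
  expect_equal(af14$af_match, 100)
  af17 <- classify_profile(rep("-", 5),
                           c("+", "-", "++", "+", "+", "+"), rule)
  expect_equal(af17$verdict, "NP")
  expect_equal(af17$np_match, 83)
  np20 <- classify_profile(c(NA, "-", "-", NA, "-"),
                           c("+", "+", "-", "+", "-", "-"), rule)
  expect_equal(np20$verdict, "undefined")  # NP match 50 < 83
})

test_that("too few available calls block a verdict", {
  rule <- panel_rule(min_available = 3)
  res <- classify_profile(c("+", "+", NA, NA, NA),
                          rep("-", 6), rule)
  expect_equal(res$verdict, "undefined")  # only 2 AF calls available
})

test_that("upgrading a minus call never flips a verdict away from its tissue", {
  rule <- panel_rule()
  set.seed(10)
  tokens <- c("-", "+", "++", NA)
  for (i in 1:200) {
    af <- sample(tokens, 5, replace = TRUE)
    np <- sample(tokens, 6, replace = TRUE)
    before <- classify_profile(af, np, rule)$verdict
    j <- which(af == "-")[1]
    if (is.na(j)) next
    af2 <- af; af2[j] <- "+"
    after <- classify_profile(af2, np, rule)$verdict
    expect_false(before == "AF" && after != "AF")
  }
})

test_that("the call-table fixture reproduces all printed match percentages", {
  cc <- classify_cohort(table5_calls())
  v <- cc$verdicts
  printed_af <- c(0, 100, 100, 0, 40, 100, 100, 100,
                  0, 0, 0, 0, 0, 0, 0, 0)
  printed_np <- c(40, 40, 0, 83, 17, 17, 0, 0,
                  20, 0, 33, 83, 50, 0, 33, 83)
  expect_equal(v$af_match, printed_af)
  expect_equal(v$np_match, printed_np)
})

test_that("cohort classification tallies verdicts and confirmations", {
  cc <- classify_cohort(table5_calls())
  s <- cc$summary
  expect_equal(s$n_af_verdict, 5)
  expect_equal(s$n_np_verdict, 3)
  expect_equal(s$n_undefined, 8)
  expect_equal(s$confirmed_af, 5)
  expect_equal(s$confirmed_np, 2)
  # the discordant sample: AF-origin #17 carries a full NP profile
  v <- cc$verdicts
  expect_equal(v$verdict[v$origin == "AF" & v$sample_id == 17], "NP")
  empty <- classify_cohort(table5_calls()[0, ])
  expect_equal(empty$summary$n_af_verdict, 0)
  expect_equal(empty$summary$n_undefined, 0)
})

test_that("clear-cohort samples fall inside fitted ranges by construction", {
  set.seed(11)
  panel <- marker_panel()
  af_expr <- matrix(rlnorm(5 * 6, log(0.1), 0.4), nrow = 5,
                    dimnames = list(panel$af_markers, NULL))
  np_expr <- matrix(rlnorm(6 * 5, log(0.3), 0.4), nrow = 6,
                    dimnames = list(panel$np_markers, NULL))
  fitted <- fit_ranges(panel, af_expr, np_expr)
  r <- fitted$ranges
  for (m in panel$af_markers) {
    lo <- r$low[r$marker == m]; hi <- r$high[r$marker == m]
    expect_true(all(call_marker(af_expr[m, ], lo, hi) %in% c("+")))
  }
})
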