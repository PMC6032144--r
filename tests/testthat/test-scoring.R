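test_that("rubric totals and flags follow the item grades", {
  expect_equal(score_rubric(rep(2, 6), "IVD"), list(total = 12L, flag = FALSE))
  expect_equal(score_rubric(rep(1, 6), "IVD"), list(total = 6L, flag = FALSE))
  expect_equal(score_rubric(c(2, 1, 0), "DD"), list(total = 3L, flag = TRUE))
  expect_equal(score_rubric(c(1, 1, 1), "DD"), list(total = 3L, flag = FALSE))
  expect_error(score_rubric(rep(1, 5), "IVD"), "6 item grades")
  expect_error(score_rubric(c(1, 3, 1), "DD"), "item 2 has grade 3")
})

test_that("identity and degeneration decision rules match their definitions", {
  expect_equal(classify_ivd(10, FALSE), "clear")
  expect_equal(classify_ivd(7, FALSE), "clear")
  expect_equal(classify_ivd(6, FALSE), "unknown")  # boundary excluded
  expect_equal(classify_ivd(9, TRUE), "unknown")
  expect_error(classify_ivd(13, FALSE), "between 0 and 12")
  expect_equal(classify_dd(4, TRUE), "severe")
  expect_equal(classify_dd(4, FALSE), "severe")
  expect_equal(classify_dd(3, FALSE), "mild")
  expect_equal(classify_dd(3, FALSE, "ge3"), "severe")
  expect_equal(classify_dd(0, FALSE), "mild")
  expect_equal(classify_dd(2, TRUE), "severe")
  expect_error(classify_dd(7, FALSE), "between 0 and 6")
})

test_that("classifying from item grades equals classifying from totals, exhaustively", {
  grids <- expand.grid(rep(list(0:2), 6))
  for (i in seq_len(nrow(grids))) {
    items <- as.integer(grids[i, ])
    sc <- score_rubric(items, "IVD")
    expect_identical(classify_ivd(sc$total, sc$flag),
                     if (sum(items) > 6 && all(items > 0)) "clear"
                     else "unknown")
  }
  grids3 <- expand.grid(rep(list(0:2), 3))
  for (i in seq_len(nrow(grids3))) {
    items <- as.integer(grids3[i, ])
    sc <- score_rubric(items, "DD")
    expect_identical(classify_dd(sc$total, sc$flag),
                     if (sum(items) > 3 || any(items == 2)) "severe"
                     else "mild")
  }
})

test_that("decision rules are monotone in single item grades", {
  grids <- expand.grid(rep(list(0:2), 6))
  for (i in seq_len(nrow(grids))) {
    items <- as.integer(grids[i, ])
    sc <- score_rubric(items, "IVD")
    before <- classify_ivd(sc$total, sc$flag)
    for (j in which(items < 2)) {
      up <- items; up[j] <- up[j] + 1L
      scu <- score_rubric(up, "IVD")
      after <- classify_ivd(scu$total, scu$flag)
      # raising a grade never demotes clear -> unknown
      expect_false(before == "clear" && after == "unknown")
    }
  }
  grids3 <- expand.grid(rep(list(0:2), 3))
  for (i in seq_len(nrow(grids3))) {
    items <- as.integer(grids3[i, ])
    sc <- score_rubric(items, "DD")
    before <- classify_dd(sc$total, sc$flag)
    for (j in which(items < 2)) {
      up <- items; up[j] <- up[j] + 1L
      scu <- score_rubric(up, "DD")
      # severe is monotone non-decreasing in each item
      expect_false(before == "severe" &&
                   classify_dd(scu$total, scu$flag) == "mild")
    }
  }
})

test_that("cohort summary reproduces the published pass counts", {
  s <- summarize_cohort(table3_records())
  expect_equal(s$n_af, 28)
  expect_equal(s$n_np, 28)
  expect_equal(s$n_af_clear, 17)
  expect_equal(s$n_np_clear, 16)
  expect_equal(s$n_af_eligible, 15)
  expect_equal(s$n_np_eligible, 11)
  expect_error(summarize_cohort(table3_records()[0, ]), "empty cohort")
})

test_that("the alternative ge3 degeneration rule yields the 38% severe rate", {
  s <- summarize_cohort(table3_records(), dd_rule = "ge3")
  expect_equal(s$n_severe, 21)
  expect_equal(round(100 * s$fraction_severe), 38)
})

test_that("single-record cohort is summarised", {
  r <- table3_records()[1, ]  # clear AF, mild
  s <- summarize_cohort(r)
  expect_equal(s$n_af_clear, 1)
  expect_equal(s$n_np, 0)
})

test_that("cohort selection keeps one eligible sample per donor and compartment", {
  sel <- select_microarray_cohort(table3_records())
  expect_equal(sel$n_af, 11)
  expect_equal(sel$n_np, 9)
  expect_equal(sel$n_donors, 13)
  expect_equal(sel$mean_age_rounded, 53L)
  expect_equal(sel$age_range, c(36, 76))
  expect_equal(sel$female_count, 6)
  expect_equal(sel$male_count, 7)
})

test_that("dedup tie-break prefers higher IVD, then lower DD, then lower id", {
  rec <- data.frame(
    donor_id = 1, gender = "f", age = 50, sample_id = c(1, 2, 3),
    disc_level = "C4/5", mri_grade = 3, compartment = "AF",
    ivd_total = c(10, 9, 10), ivd_any_zero = FALSE,
    dd_total = c(2, 1, 1), dd_any_two = FALSE)
  sel <- select_microarray_cohort(rec)
  expect_equal(sel$af_samples, 3)  # IVD 10 beats 9; DD 1 beats 2
  expect_equal(sel$n_donors, 1)
})

test_that("donor-level demographics are invariant to the tie-break rule", {
  rec <- table3_records()
  # reversing the sample-id order changes which duplicate-donor sample
  # wins ties but must not change donor-level outputs
  rec2 <- rec
  rec2$sample_id <- max(rec$sample_id) + 1 - rec$sample_id
  a <- select_microarray_cohort(rec)
  b <- select_microarray_cohort(rec2)
  expect_equal(a$donors, b$donors)
  expect_equal(a$mean_age, b$mean_age)
  expect_equal(a$female_count, b$female_count)
  expect_equal(a$male_count, b$male_count)
})

test_that("empty selection is reported as zero counts, not an error", {
  rec <- table3_records()
  rec$ivd_any_zero <- TRUE  # nothing eligible
  sel <- select_microarray_cohort(rec)
  expect_equal(sel$n_af, 0)
  expect_equal(sel$n_donors, 0)
})
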