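test_that("branch classification follows the exact P value", {
  expect_identical(classify_comparison(fourfold_table(0, 5, 5, 5)), "fragility")
  expect_identical(classify_comparison(fourfold_table(3, 10, 3, 10)), "reverse")
  expect_identical(classify_comparison(fourfold_table(2, 5, 5, 5)), "reverse")
})

test_that("median_iqr uses type-7 interpolated quartiles", {
  expect_equal(median_iqr(c(1, 2, 3)), c(median = 2, q1 = 1.5, q3 = 2.5))
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  expect_equal(median_iqr(c(0, 0, 2, 4)), c(median = 1, q1 = 0, q3 = 2.5))
  expect_equal(median_iqr(c(NA, 3)), c(median = 3, q1 = 3, q3 = 3))
  expect_error(median_iqr(numeric(0)), "at least one")
})

test_that("spearman point estimates match the rank formula", {
  expect_equal(spearman_bootstrap(1:4, c(10, 20, 30, 40), n_boot = 50, seed = 1)$rho, 1)
  expect_equal(spearman_bootstrap(1:4, c(4, 3, 2, 1), n_boot = 50, seed = 1)$rho, -1)
  r <- spearman_bootstrap(1:4, c(2, 1, 4, 3), n_boot = 200, seed = 1)
  expect_equal(r$rho, 0.6) # 1 - 6 * 4 / (4 * 15)
  expect_true(r$ci_low <= r$ci_high)
  expect_gte(r$ci_low, -1); expect_lte(r$ci_high, 1)
  expect_identical(r$n_boot, 200L)
})

test_that("bootstrap interval is seeded and covers a strong correlation", {
  set.seed(12)
  x <- rnorm(60)
  y <- x + rnorm(60, sd = 0.4)
  a <- spearman_bootstrap(x, y, n_boot = 500, seed = 99)
  b <- spearman_bootstrap(x, y, n_boot = 500, seed = 99)
  expect_identical(a$ci_low, b$ci_low)
  expect_true(a$ci_low <= a$rho && a$rho <= a$ci_high)
  expect_lt(a$p_value, 1e-6)
  expect_warning(cc <- spearman_bootstrap(rep(1, 10), 1:10, n_boot = 10, seed = 1),
                 "constant")
  expect_true(is.na(cc$rho))
})

test_that("Mood's median test reproduces hand-computed chi-square values", {
  expect_equal(moods_median_test(c(1, 2, 3), c(1, 2, 3))$chi2, 0)
  m <- moods_median_test(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(m$chi2, 8)
  expect_equal(m$p_value, stats::pchisq(8, 1, lower.tail = FALSE))
  expect_identical(m$df, 1L)
  expect_equal(m$grand_median, 4.5)
  expect_equal(unname(rowSums(m$counts)), c(4, 4))
  expect_equal(moods_median_test(c(1, 2), c(1, 2))$chi2, 0)
  expect_warning(moods_median_test(c(2, 2), c(2, 2)), "identical")
})

test_that("Mood statistic is invariant under joint monotone transforms", {
  set.seed(13)
  for (i in 1:20) {
    a <- rpois(15, 4); b <- rpois(12, 6)
    base <- moods_median_test(a, b)$chi2
    expect_equal(moods_median_test(exp(a / 3), exp(b / 3))$chi2, base)
    expect_equal(moods_median_test(2 * a + 1, 2 * b + 1)$chi2, base)
  }
})

test_that("summarize_corpus splits branches and reports finite medians", {
  s <- summarize_corpus(tiny_corpus(), n_boot = 50, seed = 1)
  expect_identical(s$n_comparisons, 4L)
  expect_identical(s$n_publications, 3L)
  expect_identical(s$branches$fragility$n, 2L)
  expect_identical(s$branches$reverse$n, 2L)
  expect_true(all(is.finite(s$branches$fragility$index)))
  expect_true(all(is.finite(s$branches$reverse$quotient)))
  # every comparison is 1:1 allocated, so the sensitivity subset is identical
  expect_identical(s$sensitivity_1to1, s$branches)
  expect_identical(s$n_non_1to1, 0L)
  # histogram masses add up to the branch sizes
  expect_equal(sum(s$histograms$fi$count), 2L)
  expect_equal(max(s$histograms$rfi$cumulative), 2L)
})

test_that("a corpus of identical tables has zero-width IQRs", {
  df <- as_trial_corpus(data.frame(
    study_id = paste0("s", 1:6), outcome_label = "o", outcome_tier = "other",
    events_intervention = 0L, n_intervention = 10L,
    events_control = 8L, n_control = 10L
  ))
  s <- summarize_corpus(df, n_boot = 20, seed = 2)
  b <- s$branches$fragility
  expect_identical(b$n, 6L)
  expect_equal(unname(b$index["q1"]), unname(b$index["q3"]))
  expect_equal(unname(b$quotient["q1"]), unname(b$quotient["q3"]))
})

test_that("summarize_corpus is deterministic given records and seed", {
  corp <- generate_corpus(corpus_config(n_comparisons = 25, seed = 4))
  s1 <- summarize_corpus(corp, n_boot = 100, seed = 77)
  s2 <- summarize_corpus(corp, n_boot = 100, seed = 77)
  s1$metrics <- NULL; s2$metrics <- NULL
  expect_identical(s1, s2)
})

test_that("an empty branch is marked absent without aborting the run", {
  df <- as_trial_corpus(data.frame(
    study_id = c("a", "b", "c"), outcome_label = "o", outcome_tier = "primary",
    events_intervention = c(3L, 4L, 5L), n_intervention = 10L,
    events_control = c(3L, 4L, 5L), n_control = 10L
  ))
  s <- summarize_corpus(df, n_boot = 20, seed = 3)
  expect_identical(s$branches$fragility$n, 0L)
  expect_null(s$branches$fragility$index)
  expect_identical(s$branches$reverse$n, 3L)
  expect_null(s$mood$fi_vs_rfi)
})
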