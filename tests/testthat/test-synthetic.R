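test_that("two-proportion sample size matches the pooled-variance formula", {
  expect_identical(required_sample_size(0.2, 0.4, 0.05, 0.8), 82L)
  expect_identical(required_sample_size(0.1, 0.3, 0.05, 0.8), 62L)
  expect_identical(required_sample_size(0.4, 0.2, 0.05, 0.8), 82L) # symmetric
  expect_error(required_sample_size(0.2, 0.2), "differ")
  expect_error(required_sample_size(0.2, 0.4, alpha = 1.2), "alpha")
  expect_error(required_sample_size(0.2, 1.4), "\\[0, 1\\]")
})

test_that("simulated trials are binomial and reproducible", {
  d <- trial_design(1, 0, n_per_group = 5, seed = 21)
  r <- simulate_trial(d, index = 1)
  expect_identical(r$events_intervention, 0L)
  expect_identical(r$events_control, 5L)

  d2 <- trial_design(0.4, 0.2, seed = 22) # n derived: 82 per arm
  expect_identical(d2$n_per_group, 82L)
  a <- simulate_trial(d2, index = 3)
  b <- simulate_trial(d2, index = 3)
  expect_identical(a, b)
  expect_false(identical(simulate_trial(d2, index = 4)$events_intervention,
                         NULL))

  # mean event count over many sub-seeds stays near n * rate
  d3 <- trial_design(0.5, 0.3, n_per_group = 100, seed = 23)
  ev <- vapply(1:1000, function(i) simulate_trial(d3, index = i)$events_intervention,
               integer(1))
  se <- sqrt(100 * 0.3 * 0.7 / 1000)
  expect_lt(abs(mean(ev) - 30), 3 * se)
})

test_that("corpus generation is byte-identical under a fixed config", {
  cfg <- corpus_config(n_comparisons = 30, seed = 91)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_corpus(corpus_config(n_comparisons = 30, seed = 92))
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("generated corpora respect the configured structure", {
  cfg <- corpus_config(n_comparisons = 300, seed = 14)
  corp <- generate_corpus(cfg)
  tot <- corp$n_intervention + corp$n_control
  expect_true(all(tot >= 30 & tot <= 243))
  expect_true(all(corp$allocation_ratio == "1:1"))
  # tier draws follow the configured multinomial within sampling error
  p <- cfg$tier_mixture
  obs <- table(factor(corp$outcome_tier, levels = names(p)))
  for (tier in names(p)) {
    se <- sqrt(300 * p[tier] * (1 - p[tier]))
    expect_lt(abs(obs[tier] - 300 * p[tier]), 4 * se)
  }
})

test_that("pooled event rates recover the generating rates", {
  corp <- generate_corpus(corpus_config(n_comparisons = 250, seed = 15))
  des <- attr(corp, "designs")
  expect_identical(nrow(des), 250L)
  for (arm in c("intervention", "control")) {
    rate <- if (arm == "intervention") des$rate_a else des$rate_b
    n <- corp[[paste0("n_", arm)]]
    ev <- corp[[paste0("events_", arm)]]
    se <- sqrt(sum(rate * (1 - rate) * n)) / sum(n)
    expect_lt(abs(sum(ev) / sum(n) - sum(rate * n) / sum(n)), 3 * se)
  }
})

test_that("an all-null mixture lands almost entirely in the reverse branch", {
  cfg <- corpus_config(n_comparisons = 200,
                       mixture = c(null = 1, powered = 0, large = 0),
                       seed = 16)
  m <- corpus_metrics(generate_corpus(cfg))
  # exact-test size is at most 5%, and conservative in small tables
  expect_gte(mean(m$direction == "reverse"), 0.95)
})

test_that("a minimally-powered mixture produces small fragility indices", {
  cfg <- corpus_config(n_comparisons = 150,
                       mixture = c(null = 0, powered = 1, large = 0),
                       seed = 17)
  m <- corpus_metrics(generate_corpus(cfg))
  frag <- m[m$direction == "fragility", ]
  expect_gt(nrow(frag), 30)
  expect_lte(median(frag$fi), 5)
})

test_that("corpus_config rejects malformed mixtures and ranges", {
  expect_error(corpus_config(mixture = c(null = 0.5, powered = 0.5, large = 0.2)),
               "sum to 1")
  expect_error(corpus_config(mixture = c(a = 1)), "null/powered/large")
  expect_error(corpus_config(size_range = c(100, 30)), "size_range")
  expect_error(corpus_config(tier_mixture = c(primary = 1, secondary = 0.2,
                                              other = 0)), "tier_mixture")
})
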