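test_that("fragility index walks the documented examples", {
  r <- fragility_index(fourfold_table(0, 5, 5, 5))
  expect_identical(r$index, 2L)
  expect_equal(r$p_trajectory, c(2 / 252, 12 / 252, 42 / 252), tolerance = 1e-12)
  expect_equal(r$quotient, 20)
  expect_identical(r$terminal_table$events_a, 2L)

  expect_identical(fragility_index(fourfold_table(3, 10, 3, 10))$index, 0L)
  expect_identical(fragility_index(fourfold_table(1, 100, 9, 100))$index, 1L)
})

test_that("fragility trajectory brackets alpha exactly once", {
  set.seed(7)
  for (i in 1:100) {
    t <- random_table(15L)
    r <- fragility_index(t, alpha = 0.05)
    tr <- r$p_trajectory
    if (is.na(r$index)) next
    if (r$index == 0L) {
      expect_length(tr, 1L)
      expect_gte(tr[1], 0.05)
    } else {
      expect_length(tr, r$index + 1L)
      expect_true(all(tr[-length(tr)] < 0.05))
      expect_gte(tr[length(tr)], 0.05)
      expect_identical(total_n(r$terminal_table), total_n(t))
    }
  }
})

test_that("fragility index is non-decreasing in alpha", {
  # the walk's path is alpha-independent, so a larger alpha means the
  # trajectory crosses the threshold no earlier: FI can only grow
  set.seed(8)
  alphas <- c(0.01, 0.05, 0.1, 0.2)
  for (i in 1:40) {
    t <- random_table(15L)
    idx <- vapply(alphas, function(a) {
      k <- fragility_index(t, a)$index
      if (is.na(k)) Inf else as.numeric(k)
    }, numeric(1))
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("fragility walk continues in the other arm on saturation", {
  # an all-events intervention arm with fewer events than a large, mostly
  # event-free control arm: the walk must flag saturation and switch arms
  found <- FALSE
  for (na in 2:5) {
    t <- fourfold_table(na, na, na + 1, 30)
    r <- fragility_index(t)
    if (!is.na(r$index) && r$saturated) {
      found <- TRUE
      expect_identical(r$index, oracle_fi(na, na, na + 1L, 30L))
      expect_gte(r$p_trajectory[length(r$p_trajectory)], 0.05)
    }
  }
  expect_true(found)
})

test_that("reverse fragility index finds the documented minima", {
  expect_identical(reverse_fragility_index(fourfold_table(2, 5, 5, 5))$index, 1L)
  expect_identical(reverse_fragility_index(fourfold_table(0, 5, 5, 5))$index, 0L)
  r <- reverse_fragility_index(fourfold_table(5, 10, 5, 10))
  expect_identical(r$index, 5L)
  expect_lt(r$p_trajectory[length(r$p_trajectory)], 0.05)
  # two patients per arm cannot reach significance at all
  expect_true(is.na(reverse_fragility_index(fourfold_table(1, 2, 1, 2))$index))
})

test_that("greedy reverse strategy never beats the exact minimum", {
  set.seed(9)
  for (i in 1:60) {
    t <- random_table(12L)
    ex <- reverse_fragility_index(t, strategy = "exact")
    gr <- reverse_fragility_index(t, strategy = "greedy-toward-separation")
    if (!is.na(gr$index)) {
      expect_false(is.na(ex$index))
      expect_lte(ex$index, gr$index)
    }
  }
})

test_that("indices match the independent oracles on random tables", {
  set.seed(10)
  for (i in 1:60) {
    t <- random_table(15L)
    expect_identical(fragility_index(t)$index,
                     oracle_fi(t$events_a, t$size_a, t$events_b, t$size_b))
    expect_identical(reverse_fragility_index(t)$index,
                     oracle_rfi(t$events_a, t$size_a, t$events_b, t$size_b))
  }
})

test_that("fragility quotient is the index as a percent of total N", {
  expect_equal(fragility_quotient(2, 10), 20)
  expect_equal(fragility_quotient(0, 50), 0)
  expect_equal(round(fragility_quotient(1, 30), 2), 3.33)
  expect_true(is.na(fragility_quotient(NA_integer_, 10)))
  expect_error(fragility_quotient(1, 1), "at least 2")
  expect_error(fragility_quotient(-1, 10), "non-negative")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:400, 1)
    k <- sample(0:n, 1)
    q <- fragility_quotient(k, n)
    expect_gte(q, 0); expect_lte(q, 100)
  }
})

test_that("comparison_metrics assembles a consistent metric block", {
  m <- comparison_metrics(fourfold_table(0, 5, 5, 5))
  expect_identical(m$fi, 2L)
  expect_equal(m$fi_quotient_pct, 20)
  expect_identical(m$rfi, 0L)
  expect_identical(m$direction, "fragility")
  expect_equal(m$s_value, -log2(m$fisher_p))
  m2 <- comparison_metrics(fourfold_table(1, 2, 1, 2))
  expect_true(is.na(m2$rfi))
  expect_match(m2$warnings, "rfi_not_attainable")
})
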