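# Independent oracles used against the package implementation. These
# deliberately go through stats::fisher.test (never the package's own
# p-value code) so the two routes stay independent.

oracle_p <- function(ea, na, eb, nb) {
  stats::fisher.test(matrix(c(ea, na - ea, eb, nb - eb), 2, 2))$p.value
}

# stepwise replay of the fragility walk: add events to the arm with
# fewer events (tie -> smaller arm, then arm A; saturated -> other arm)
# until fisher.test's two-sided p reaches alpha
oracle_fi <- function(ea, na, eb, nb, alpha = 0.05) {
  k <- 0L
  while (oracle_p(ea, na, eb, nb) < alpha) {
    arm <- if (ea < eb) "a"
    else if (eb < ea) "b"
    else if (nb < na) "b"
    else "a"
    if (arm == "a" && ea == na) arm <- "b"
    if (arm == "b" && eb == nb) arm <- "a"
    if (arm == "a" && ea == na) return(NA_integer_) # both saturated
    if (arm == "a") ea <- ea + 1L else eb <- eb + 1L
    k <- k + 1L
  }
  k
}

# brute-force minimum L1 distance to any significant cell of the full
# outcome grid
oracle_rfi <- function(ea, na, eb, nb, alpha = 0.05) {
  if (oracle_p(ea, na, eb, nb) < alpha) return(0L)
  best <- NA_integer_
  for (a in 0:na) {
    for (b in 0:nb) {
      if (oracle_p(a, na, b, nb) < alpha) {
        d <- abs(a - ea) + abs(b - eb)
        if (is.na(best) || d < best) best <- d
      }
    }
  }
  best
}

# fisher.test p over the whole grid, cached per margin pair (speeds up
# exhaustive oracle scans)
oracle_p_grid <- local({
  cache <- new.env(parent = emptyenv())
  function(na, nb) {
    key <- paste(na, nb)
    if (!is.null(cache[[key]])) return(cache[[key]])
    G <- matrix(NA_real_, na + 1L, nb + 1L)
    for (a in 0:na) for (b in 0:nb) G[a + 1L, b + 1L] <- oracle_p(a, na, b, nb)
    cache[[key]] <- G
    G
  }
})

random_table <- function(max_n = 15L) {
  na <- sample(1:max_n, 1L)
  nb <- sample(1:max_n, 1L)
  fourfold_table(sample(0:na, 1L), na, sample(0:nb, 1L), nb)
}

tiny_corpus <- function() {
  as_trial_corpus(data.frame(
    study_id = c("s1", "s1", "s2", "s3"),
    outcome_label = c("death", "reoperation", "infection", "leak"),
    outcome_tier = c("primary", "secondary", "primary", "other"),
    events_intervention = c(0L, 1L, 3L, 8L),
    n_intervention = c(12L, 100L, 10L, 25L),
    events_control = c(9L, 9L, 3L, 10L),
    n_control = c(12L, 100L, 10L, 25L),
    stringsAsFactors = FALSE
  ))
}
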