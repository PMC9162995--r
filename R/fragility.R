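#' Fragility index of a significant comparison
#'
#' Starting from a 2x2 table significant under Fisher's exact test, events
#' are added one patient at a time to the arm with fewer events (a
#' non-event becomes an event; arm sizes are fixed) until the two-sided P
#' value first reaches or exceeds `alpha`. The number of conversions is
#' the fragility index. A baseline P of `alpha` or more gives index 0, so
#' nominally significant comparisons whose Fisher P lands at 0.05 or above
#' are recorded as maximally fragile rather than excluded.
#'
#' Ties in event counts are broken toward the smaller arm, then toward arm
#' A; for 1:1 trials with distinct counts the rule never engages. If the
#' chosen arm saturates (all patients are events) the walk continues in
#' the other arm and a warning flag is set; if both arms saturate while P
#' is still below `alpha` the index is not attainable and `NA` is
#' returned.
#'
#' @param table A [fourfold_table()].
#' @param alpha Significance level (default 0.05).
#' @return A `fragility_result` list: `direction` (`"fragility"`),
#'   `index` (integer, `NA` if not attainable), `quotient` (percent of
#'   total N), `p_trajectory` (baseline P first, then P after each
#'   conversion), `terminal_table`, `saturated` flag, `alpha`.
#' @examples
#' fragility_index(fourfold_table(0, 5, 5, 5)) # index 2
#' @export
fragility_index <- function(table, alpha = 0.05) {
  validate_fourfold(table)
  check_alpha(alpha)
  cur <- table
  traj <- fisher_exact_p(cur)
  saturated <- FALSE
  while (p_below_alpha(traj[length(traj)], alpha)) {
    arm <- smaller_event_arm(cur)
    if (cur[[paste0("events_", arm)]] == cur[[paste0("size_", arm)]]) {
      arm <- setdiff(c("a", "b"), arm)
      saturated <- TRUE
      if (cur[[paste0("events_", arm)]] == cur[[paste0("size_", arm)]]) {
        return(new_fragility_result("fragility", NA_integer_, table, cur,
                                    traj, alpha, saturated = TRUE))
      }
    }
    cur[[paste0("events_", arm)]] <- cur[[paste0("events_", arm)]] + 1L
    traj <- c(traj, fisher_exact_p(cur))
  }
  new_fragility_result("fragility", length(traj) - 1L, table, cur, traj,
                       alpha, saturated = saturated)
}

smaller_event_arm <- function(t) {
  if (t$events_a < t$events_b) return("a")
  if (t$events_b < t$events_a) return("b")
  if (t$size_b < t$size_a) "b" else "a"
}

#' Reverse fragility index of a nonsignificant comparison
#'
#' The minimum number of single-patient outcome switches (each switch
#' flips one patient's event status in either arm; arm sizes are fixed)
#' that turns a nonsignificant table into one with two-sided Fisher
#' P < `alpha`. A baseline P below `alpha` gives index 0.
#'
#' The default `"exact"` strategy takes the literal minimum: the smallest
#' L1 distance `|delta events_a| + |delta events_b|` to any significant
#' cell of the full `(size_a + 1) x (size_b + 1)` outcome grid, found by
#' exhaustive scan. The `"greedy-toward-separation"` strategy instead
#' walks one switch at a time, always taking the single switch that most
#' decreases P, and stops at the first significant table; it can only
#' reach the exact minimum or overshoot it, and is provided for
#' comparability with stepwise calculators.
#'
#' If no cell of the grid is significant (tiny arms), the index is not
#' attainable and `NA` is returned.
#'
#' @inheritParams fragility_index
#' @param strategy `"exact"` (grid minimum) or
#'   `"greedy-toward-separation"` (stepwise walk).
#' @return A `fragility_result` list as in [fragility_index()], with
#'   `direction = "reverse"`. For the exact strategy the trajectory holds
#'   the baseline P and the terminal P (intermediate single-switch tables
#'   on a shortest path are not unique); the greedy strategy records P
#'   after every switch.
#' @examples
#' reverse_fragility_index(fourfold_table(5, 10, 5, 10)) # index 5
#' @export
reverse_fragility_index <- function(table, alpha = 0.05,
                                    strategy = c("exact", "greedy-toward-separation")) {
  validate_fourfold(table)
  check_alpha(alpha)
  strategy <- match.arg(strategy)
  p0 <- fisher_exact_p(table)
  if (p_below_alpha(p0, alpha)) {
    return(new_fragility_result("reverse", 0L, table, table, p0, alpha))
  }
  if (strategy == "exact") rfi_exact(table, alpha, p0) else rfi_greedy(table, alpha, p0)
}

rfi_exact <- function(table, alpha, p0) {
  G <- fisher_p_grid(table$size_a, table$size_b)
  sig <- which(p_below_alpha(G, alpha), arr.ind = TRUE)
  if (nrow(sig) == 0L) {
    return(new_fragility_result("reverse", NA_integer_, table, table, p0, alpha))
  }
  dist <- abs(sig[, 1L] - 1L - table$events_a) + abs(sig[, 2L] - 1L - table$events_b)
  best <- which.min(dist)
  term <- table
  term$events_a <- as.integer(sig[best, 1L] - 1L)
  term$events_b <- as.integer(sig[best, 2L] - 1L)
  new_fragility_result("reverse", as.integer(dist[best]), table, term,
                       c(p0, G[sig[best, 1L], sig[best, 2L]]), alpha)
}

rfi_greedy <- function(table, alpha, p0) {
  G <- fisher_p_grid(table$size_a, table$size_b)
  if (!any(p_below_alpha(G, alpha))) {
    return(new_fragility_result("reverse", NA_integer_, table, table, p0, alpha))
  }
  cur <- c(table$events_a, table$events_b)
  traj <- p0
  repeat {
    moves <- rbind(
      c(cur[1L] + 1L, cur[2L]), c(cur[1L] - 1L, cur[2L]),
      c(cur[1L], cur[2L] + 1L), c(cur[1L], cur[2L] - 1L)
    )
    ok <- moves[, 1L] >= 0L & moves[, 1L] <= table$size_a &
      moves[, 2L] >= 0L & moves[, 2L] <= table$size_b
    moves <- moves[ok, , drop = FALSE]
    ps <- G[cbind(moves[, 1L] + 1L, moves[, 2L] + 1L)]
    best <- which.min(ps)
    if (ps[best] >= traj[length(traj)]) {
      # local minimum of the p surface without crossing alpha
      return(new_fragility_result("reverse", NA_integer_, table,
                                  grid_table(table, cur), traj, alpha))
    }
    cur <- moves[best, ]
    traj <- c(traj, ps[best])
    if (p_below_alpha(ps[best], alpha)) {
      return(new_fragility_result("reverse", length(traj) - 1L, table,
                                  grid_table(table, cur), traj, alpha))
    }
  }
}

grid_table <- function(table, cells) {
  table$events_a <- as.integer(cells[1L])
  table$events_b <- as.integer(cells[2L])
  table
}

new_fragility_result <- function(direction, index, baseline, terminal,
                                 trajectory, alpha, saturated = FALSE) {
  structure(
    list(
      direction = direction,
      index = index,
      quotient = fragility_quotient(index, total_n(baseline)),
      p_trajectory = as.numeric(trajectory),
      baseline_table = baseline,
      terminal_table = terminal,
      saturated = saturated,
      alpha = alpha
    ),
    class = "fragility_result"
  )
}

#' @export
print.fragility_result <- function(x, ...) {
  lab <- if (x$direction == "fragility") "Fragility index" else "Reverse fragility index"
  if (is.na(x$index)) {
    cat(sprintf("%s: not attainable (alpha = %g)\n", lab, x$alpha))
  } else {
    cat(sprintf("%s: %d (quotient %.4g%% of N = %d, alpha = %g)\n",
                lab, x$index, x$quotient, total_n(x$baseline_table), x$alpha))
  }
  invisible(x)
}

#' Fragility quotient
#'
#' The (reverse) fragility index divided by the trial's total sample size
#' and multiplied by 100, i.e. expressed as a percent, which avoids
#' excessively small numbers.
#'
#' @param index Fragility or reverse fragility index (`NA` passes
#'   through).
#' @param n Total sample size of the comparison.
#' @return `100 * index / n`, in percent.
#' @examples
#' fragility_quotient(2, 10) # 20
#' @export
fragility_quotient <- function(index, n) {
  if (any(n[!is.na(n)] < 2)) stop("total sample size must be at least 2", call. = FALSE)
  if (any(index[!is.na(index)] < 0)) stop("index must be non-negative", call. = FALSE)
  100 * index / n
}

#' All per-comparison metrics of one 2x2 table
#'
#' Convenience wrapper computing the full metric block for one comparison:
#' exact P, S-value, relative risk, fragility and reverse fragility
#' indices with quotients, classification branch, and exact post-hoc power
#' at the observed arm proportions.
#'
#' @inheritParams fragility_index
#' @param rfi_strategy Passed to [reverse_fragility_index()].
#' @param power_seed Seed for the Monte Carlo fallback of
#'   [posthoc_power()] (unused when full enumeration applies).
#' @return A one-row `data.frame` with columns `fisher_p`, `s_value`,
#'   `rr`, `fi`, `fi_quotient_pct`, `rfi`, `rfi_quotient_pct`,
#'   `posthoc_power`, `power_method`, `direction`, `warnings`.
#' @export
comparison_metrics <- function(table, alpha = 0.05,
                               rfi_strategy = c("exact", "greedy-toward-separation"),
                               power_seed = 2014L) {
  validate_fourfold(table)
  check_alpha(alpha)
  rfi_strategy <- match.arg(rfi_strategy)
  p <- fisher_exact_p(table)
  fi <- fragility_index(table, alpha)
  rfi <- reverse_fragility_index(table, alpha, rfi_strategy)
  pow <- posthoc_power(
    size_a = table$size_a, size_b = table$size_b,
    rate_a = table$events_a / table$size_a,
    rate_b = table$events_b / table$size_b,
    alpha = alpha, seed = power_seed
  )
  rr <- if (table$events_b == 0L) NA_real_ else
    (table$events_a / table$size_a) / (table$events_b / table$size_b)
  warnings <- c(
    if (fi$saturated) "fi_arm_saturated",
    if (is.na(fi$index)) "fi_not_attainable",
    if (is.na(rfi$index)) "rfi_not_attainable",
    if (table$events_b == 0L) "rr_undefined"
  )
  data.frame(
    fisher_p = p,
    s_value = s_value(p),
    rr = rr,
    fi = fi$index,
    fi_quotient_pct = fi$quotient,
    rfi = rfi$index,
    rfi_quotient_pct = rfi$quotient,
    posthoc_power = pow$power,
    power_method = pow$method,
    direction = if (p_below_alpha(p, alpha)) "fragility" else "reverse",
    warnings = paste(warnings, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
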