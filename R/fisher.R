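# Conditional exact p-values for 2x2 tables with both margins fixed.
#
# The two-sided p uses the minimum-likelihood rule: conditioning on the
# margins makes the intervention-arm event count hypergeometric, and the p
# is the sum of point probabilities no greater than (1 + 1e-7) times the
# observed one -- the convention of stats::fisher.test, against which the
# implementation is tested. The grid form exists because the reverse
# fragility search and exact power enumeration need p for every cell of
# the (size_a + 1) x (size_b + 1) outcome grid, where per-table calls are
# wasteful: within one diagonal (fixed event total k) all cells share one
# hypergeometric distribution.

REL_TOL <- 1e-7

# Guarded alpha comparison used by every significance decision in the
# package. Exact p-values are rationals; a table can hit alpha exactly
# (e.g. p = 1/20 at alpha = 0.05), where naive floating summation may
# land one ulp below and flip the strict comparison. Achievable p-values
# other than alpha itself sit many orders of magnitude further away than
# this guard at trial-scale tables, so only the knife-edge case is
# affected -- and it classifies as nonsignificant, as the strict rule on
# the exact rational demands.
ALPHA_GUARD <- 1e-9

p_below_alpha <- function(p, alpha) p < alpha * (1 - ALPHA_GUARD)

#' Two-sided conditional exact P values over a full outcome grid
#'
#' Computes the two-sided Fisher P value for every table
#' `(x_a / size_a, x_b / size_b)` with `x_a` in `0:size_a` and `x_b` in
#' `0:size_b`, by enumerating the hypergeometric distribution on each
#' anti-diagonal (fixed event total) once.
#'
#' @param size_a,size_b Arm sizes.
#' @return A `(size_a + 1) x (size_b + 1)` matrix; entry `[i, j]` is the P
#'   value of the table with `i - 1` intervention and `j - 1` control
#'   events.
#' @examples
#' G <- fisher_p_grid(5, 5)
#' G[1, 6] # 0/5 vs 5/5
#' @export
fisher_p_grid <- function(size_a, size_b) {
  size_a <- as.integer(size_a); size_b <- as.integer(size_b)
  if (size_a < 1L || size_b < 1L) stop("arm sizes must be at least 1", call. = FALSE)
  P <- matrix(NA_real_, size_a + 1L, size_b + 1L)
  for (k in 0:(size_a + size_b)) {
    lo <- max(0L, k - size_b)
    hi <- min(size_a, k)
    x <- lo:hi
    d <- stats::dhyper(x, size_a, size_b, k)
    # sort once per diagonal; cumulative sum gives all minimum-likelihood
    # tail sums at O(m log m) instead of O(m^2)
    o <- order(d)
    cs <- cumsum(d[o])
    thr <- d * (1 + REL_TOL)
    idx <- findInterval(thr, d[o])
    P[cbind(x + 1L, k - x + 1L)] <- pmin(cs[pmax(idx, 1L)], 1)
  }
  P
}

#' Two-sided Fisher exact P value of one comparison
#'
#' Conditional on both margins, sums the hypergeometric point
#' probabilities no greater than the observed table's (minimum-likelihood
#' two-sided rule). Equals `stats::fisher.test()`'s two-sided P value.
#'
#' @param table A [fourfold_table()].
#' @return The P value, in (0, 1].
#' @examples
#' fisher_exact_p(fourfold_table(0, 5, 5, 5)) # 2/252
#' @export
fisher_exact_p <- function(table) {
  validate_fourfold(table)
  k <- table$events_a + table$events_b
  lo <- max(0L, k - table$size_b)
  hi <- min(table$size_a, k)
  d <- stats::dhyper(lo:hi, table$size_a, table$size_b, k)
  obs <- d[table$events_a - lo + 1L]
  min(sum(d[d <= obs * (1 + REL_TOL)]), 1)
}

#' Exact test result with S-value and significance flag
#'
#' @param table A [fourfold_table()].
#' @param alpha Significance level; a comparison is significant when
#'   `p_value < alpha` (strict).
#' @return A `fisher_result` list: `p_value`, `s_value` (bits),
#'   `significant`, `alpha`.
#' @export
fisher_result <- function(table, alpha = 0.05) {
  check_alpha(alpha)
  p <- fisher_exact_p(table)
  structure(
    list(p_value = p, s_value = s_value(p),
         significant = p_below_alpha(p, alpha), alpha = alpha),
    class = "fisher_result"
  )
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf(
    "Fisher exact: P = %.4g, S = %.2f bits, %s at alpha = %g\n",
    x$p_value, x$s_value,
    if (x$significant) "significant" else "not significant", x$alpha
  ))
  invisible(x)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  invisible(alpha)
}
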