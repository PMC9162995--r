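#' Exact power of the two-sided Fisher test for two binomial arms
#'
#' The power is the probability that two independent binomial arms
#' produce a table significant under the two-sided exact test:
#' the sum over all outcome pairs `(x_a, x_b)` of
#' `dbinom(x_a, size_a, rate_a) * dbinom(x_b, size_b, rate_b)` restricted
#' to pairs with conditional exact P below `alpha`. For post-hoc use the
#' rates are the observed arm proportions, which makes the result a pure
#' function of the observed table.
#'
#' Full enumeration over the outcome grid is used when
#' `(size_a + 1) * (size_b + 1) <= max_enum`; beyond that the same
#' quantity is estimated by seeded Monte Carlo draws of the two arms. The
#' method actually used is recorded in the result.
#'
#' @param size_a,size_b Patients per arm.
#' @param rate_a,rate_b True (or observed) event probabilities in
#'   \[0, 1\].
#' @param alpha Significance level of the exact test.
#' @param max_enum Largest outcome-grid size enumerated exactly.
#' @param n_mc Monte Carlo draws used beyond `max_enum`.
#' @param seed Seed for the Monte Carlo path; enumeration ignores it.
#' @return A list with `power`, `method` (`"enumeration"` or
#'   `"monte-carlo"`), `n_mc` (`NA` under enumeration), and the echoed
#'   inputs.
#' @examples
#' posthoc_power(5, 5, 0.1, 0.9)$power # ~ 0.736
#' @export
posthoc_power <- function(size_a, size_b, rate_a, rate_b, alpha = 0.05,
                          max_enum = 4e6, n_mc = 1e5, seed = 2014L) {
  size_a <- as.integer(size_a); size_b <- as.integer(size_b)
  if (size_a < 1L || size_b < 1L) stop("arm sizes must be at least 1", call. = FALSE)
  if (any(c(rate_a, rate_b) < 0) || any(c(rate_a, rate_b) > 1))
    stop("event rates must lie in [0, 1]", call. = FALSE)
  check_alpha(alpha)

  if ((size_a + 1) * (size_b + 1) <= max_enum) {
    G <- fisher_p_grid(size_a, size_b)
    pa <- stats::dbinom(0:size_a, size_a, rate_a)
    pb <- stats::dbinom(0:size_b, size_b, rate_b)
    power <- as.numeric(pa %*% p_below_alpha(G, alpha) %*% pb)
    method <- "enumeration"
    n_mc <- NA_integer_
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    xa <- stats::rbinom(n_mc, size_a, rate_a)
    xb <- stats::rbinom(n_mc, size_b, rate_b)
    # p only for distinct outcome pairs actually drawn
    key <- paste(xa, xb)
    uk <- !duplicated(key)
    pu <- mapply(
      function(a, b) fisher_exact_p(fourfold_table(a, size_a, b, size_b)),
      xa[uk], xb[uk]
    )
    names(pu) <- key[uk]
    power <- mean(p_below_alpha(pu[key], alpha))
    method <- "monte-carlo"
  }
  list(power = power, method = method, n_mc = n_mc,
       size_a = size_a, size_b = size_b, rate_a = rate_a, rate_b = rate_b,
       alpha = alpha, seed = seed)
}

# save/restore the global RNG state so seeded internals do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
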