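#' Construct a 2x2 trial-comparison table
#'
#' The unit of all fragility computation: one two-arm comparison with a
#' dichotomous outcome, stored as event counts and arm sizes. Arm A is the
#' intervention arm by convention, so relative risks read treatment over
#' control.
#'
#' @param events_a Events in arm A (intervention).
#' @param size_a Patients in arm A.
#' @param events_b Events in arm B (control).
#' @param size_b Patients in arm B.
#'
#' @return An object of class `fourfold_table` with integer fields
#'   `events_a`, `size_a`, `events_b`, `size_b`.
#'
#' @examples
#' fourfold_table(1, 100, 9, 100)
#' @export
fourfold_table <- function(events_a, size_a, events_b, size_b) {
  x <- list(
    events_a = as.integer(events_a), size_a = as.integer(size_a),
    events_b = as.integer(events_b), size_b = as.integer(size_b)
  )
  class(x) <- "fourfold_table"
  validate_fourfold(x)
  x
}

validate_fourfold <- function(x) {
  f <- unlist(x[c("events_a", "size_a", "events_b", "size_b")])
  if (anyNA(f)) stop("fourfold_table cells must be non-missing integers", call. = FALSE)
  if (x$size_a < 1L || x$size_b < 1L)
    stop("arm sizes must be at least 1", call. = FALSE)
  if (x$events_a < 0L || x$events_b < 0L)
    stop("event counts must be non-negative", call. = FALSE)
  if (x$events_a > x$size_a || x$events_b > x$size_b)
    stop("event count exceeds arm size", call. = FALSE)
  invisible(x)
}

#' @export
print.fourfold_table <- function(x, ...) {
  cat(sprintf(
    "2x2 comparison: %d/%d (intervention) vs %d/%d (control), N = %d\n",
    x$events_a, x$size_a, x$events_b, x$size_b, total_n(x)
  ))
  invisible(x)
}

#' @export
as.matrix.fourfold_table <- function(x, ...) {
  matrix(
    c(x$events_a, x$size_a - x$events_a, x$events_b, x$size_b - x$events_b),
    nrow = 2L,
    dimnames = list(c("event", "no event"), c("intervention", "control"))
  )
}

#' Total sample size of a comparison
#'
#' @param table A [fourfold_table()].
#' @return `size_a + size_b`.
#' @export
total_n <- function(table) {
  table$size_a + table$size_b
}

#' Relative risk of an event, intervention over control
#'
#' No continuity correction is applied: a zero event count in the control
#' arm leaves the ratio undefined and returns `NA` with a warning.
#'
#' @param table A [fourfold_table()].
#' @return The risk ratio `(events_a/size_a) / (events_b/size_b)`.
#' @examples
#' relative_risk(fourfold_table(1, 100, 9, 100)) # ~ 0.11
#' @export
relative_risk <- function(table) {
  validate_fourfold(table)
  if (table$events_b == 0L) {
    warning("relative risk undefined: no events in the control arm", call. = FALSE)
    return(NA_real_)
  }
  (table$events_a / table$size_a) / (table$events_b / table$size_b)
}

#' Shannon S-value (surprisal) of a P value
#'
#' Transforms a P value into bits of information against the test
#' hypothesis, `-log2(p)`: an S-value of s carries the same surprise as s
#' consecutive heads from a fair coin. P = 1 maps to 0 bits.
#'
#' @param p P value(s) in (0, 1]; vectorised.
#' @return The surprisal in bits.
#' @examples
#' s_value(0.039) # ~ 4.68 bits
#' s_value(0.5)   # exactly one coin toss
#' @export
s_value <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]", call. = FALSE)
  0 - log2(p) # the leading 0 turns -log2(1) = -0 into +0
}
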