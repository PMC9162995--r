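#' Classify a comparison into the fragility or reverse branch
#'
#' The fragility index applies to comparisons significant under the
#' two-sided exact test, the reverse fragility index to the rest; the
#' branch is therefore a deterministic function of the Fisher P value.
#'
#' @param table A [fourfold_table()].
#' @param alpha Significance level.
#' @return `"fragility"` if `fisher_exact_p(table) < alpha`, else
#'   `"reverse"`.
#' @export
classify_comparison <- function(table, alpha = 0.05) {
  check_alpha(alpha)
  if (p_below_alpha(fisher_exact_p(table), alpha)) "fragility" else "reverse"
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation of order statistics
#' (`stats::quantile` type 7), which yields fractional medians such as
#' 1.5 for integer-valued indices.
#'
#' @param x Numeric values; `NA`s (sentinels excluded upstream) are
#'   dropped.
#' @return Named vector `c(median, q1, q3)`.
#' @examples
#' median_iqr(c(0, 0, 2, 4)) # 1, 0, 2.5
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("median_iqr needs at least one finite value", call. = FALSE)
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1L], q1 = q[2L], q3 = q[3L])
}

#' Spearman rank correlation with a bootstrap percentile interval
#'
#' The point estimate is the average-rank Spearman rho on the full
#' sample; the confidence interval is the percentile interval of rho over
#' paired (case) resamples; the P value uses the t approximation with
#' n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, length at least 3.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Seed for the resampling stream.
#' @param conf Confidence level of the percentile interval.
#' @return A `correlation_result` list: `rho`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `n_boot`, `seed`, `conf`. A constant margin flags
#'   `rho` as `NA` with a warning.
#' @examples
#' spearman_bootstrap(1:4, c(2, 1, 4, 3), n_boot = 200, seed = 1)
#' @export
spearman_bootstrap <- function(x, y, n_boot = 10000L, seed = 2014L, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop("spearman_bootstrap needs paired vectors of length >= 3", call. = FALSE)
  if (n_boot < 1L) stop("n_boot must be at least 1", call. = FALSE)
  out <- structure(
    list(rho = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         p_value = NA_real_, n = n, n_boot = as.integer(n_boot),
         seed = as.integer(seed), conf = conf),
    class = "correlation_result"
  )
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: constant margin", call. = FALSE)
    return(out)
  }
  rho <- stats::cor(x, y, method = "spearman")
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  out$rho <- rho
  out$p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boot <- apply(idx, 2L, function(i) {
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i], method = "spearman")
  })
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE, type = 7)
  out$ci_low <- qs[1L]
  out$ci_high <- qs[2L]
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Spearman rho = %.3g, %g%% bootstrap CI [%.3g, %.3g], P = %.4g (n = %d, %d resamples)\n",
    x$rho, 100 * x$conf, x$ci_low, x$ci_high, x$p_value, x$n, x$n_boot
  ))
  invisible(x)
}

#' Mood's median test for two samples
#'
#' Classifies every observation as above versus at-or-below the pooled
#' grand median and applies the Pearson chi-square test without
#' continuity correction to the resulting 2x2 classification table
#' (df = 1). Ties with the grand median count as "at or below".
#'
#' @param sample_1,sample_2 Nonempty numeric vectors (`NA`s dropped).
#' @return A `mood_result` list: `chi2`, `df`, `p_value`,
#'   `grand_median`, `counts` (2x2 classification table), `warning`.
#' @examples
#' moods_median_test(1:4, 5:8) # chi2 = 8
#' @export
moods_median_test <- function(sample_1, sample_2) {
  sample_1 <- sample_1[!is.na(sample_1)]
  sample_2 <- sample_2[!is.na(sample_2)]
  if (length(sample_1) == 0L || length(sample_2) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  pooled <- c(sample_1, sample_2)
  gm <- stats::median(pooled)
  counts <- rbind(
    sample_1 = c(above = sum(sample_1 > gm), at_or_below = sum(sample_1 <= gm)),
    sample_2 = c(above = sum(sample_2 > gm), at_or_below = sum(sample_2 <= gm))
  )
  warn <- NA_character_
  if (all(pooled == pooled[1L]) || sum(counts[, "above"]) == 0L) {
    chi2 <- 0
    p <- 1
    if (all(pooled == pooled[1L])) {
      warn <- "all pooled values identical"
      warning(warn, call. = FALSE)
    }
  } else {
    e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    chi2 <- sum((counts - e)^2 / e)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    list(chi2 = chi2, df = 1L, p_value = p, grand_median = gm,
         counts = counts, warning = warn),
    class = "mood_result"
  )
}

#' @export
print.mood_result <- function(x, ...) {
  cat(sprintf("Mood's median test: chi2 = %.4g, df = %d, P = %.4g (grand median %.4g)\n",
              x$chi2, x$df, x$p_value, x$grand_median))
  invisible(x)
}

#' Corpus-level summary of fragility metrics
#'
#' Computes the full results battery over a corpus of trial comparisons:
#' branch classification, per-branch medians and interquartile ranges of
#' the indices and quotients, bootstrap Spearman correlations between
#' indices, P values, sample sizes and post-hoc power, Mood's median
#' tests between branches, histogram/cumulative tables of the index and
#' quotient distributions, and a sensitivity variant restricted to
#' 1:1-allocated comparisons.
#'
#' The correlation battery pairs each index with the P values and total
#' sample sizes of its own branch; the power correlations pair post-hoc
#' power with P over all comparisons and with each index over that
#' index's branch (`power_correlations = "pooled"` instead pools the
#' index-power pairs across branches). Comparisons are the analysis
#' unit; no within-study clustering adjustment is applied. Unattainable
#' (sentinel) indices are excluded from medians and correlations and
#' counted separately.
#'
#' @param corpus A `trial_corpus`, or a metrics table from
#'   [corpus_metrics()] (recognised by its metric columns and not
#'   recomputed).
#' @param alpha Significance level for classification and the index
#'   walks.
#' @param n_boot Bootstrap resamples per correlation.
#' @param seed Seed for all bootstrap streams.
#' @param rfi_strategy Passed to [reverse_fragility_index()].
#' @param power_correlations `"branch"` (default) or `"pooled"`, see
#'   Details.
#' @return A `corpus_summary` list; see the package vignette for the
#'   field-by-field description.
#' @export
summarize_corpus <- function(corpus, alpha = 0.05, n_boot = 10000L,
                             seed = 2014L,
                             rfi_strategy = c("exact", "greedy-toward-separation"),
                             power_correlations = c("branch", "pooled")) {
  rfi_strategy <- match.arg(rfi_strategy)
  power_correlations <- match.arg(power_correlations)
  check_alpha(alpha)
  m <- if (all(c("fisher_p", "fi", "rfi", "posthoc_power") %in% names(corpus)))
    corpus
  else
    corpus_metrics(corpus, alpha = alpha, rfi_strategy = rfi_strategy,
                   power_seed = seed)

  frag <- m[m$direction == "fragility", , drop = FALSE]
  rev_ <- m[m$direction == "reverse", , drop = FALSE]

  branch_stats <- function(d, index_col, quot_col) {
    if (nrow(d) == 0L || all(is.na(d[[index_col]])))
      return(list(n = nrow(d), n_sentinel = sum(is.na(d[[index_col]])),
                  index = NULL, quotient = NULL))
    list(
      n = nrow(d),
      n_sentinel = sum(is.na(d[[index_col]])),
      index = median_iqr(d[[index_col]]),
      quotient = median_iqr(d[[quot_col]])
    )
  }

  cor_or_null <- function(x, y, boot_seed) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) return(NULL)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NULL)
    spearman_bootstrap(x[ok], y[ok], n_boot = n_boot, seed = boot_seed)
  }

  pow_fi_d <- if (power_correlations == "branch") frag else m
  pow_rfi_d <- if (power_correlations == "branch") rev_ else m
  correlations <- list(
    fi_vs_p = cor_or_null(frag$fi, frag$fisher_p, seed),
    fi_vs_n = cor_or_null(frag$fi, frag$total_n, seed + 1L),
    rfi_vs_p = cor_or_null(rev_$rfi, rev_$fisher_p, seed + 2L),
    rfi_vs_n = cor_or_null(rev_$rfi, rev_$total_n, seed + 3L),
    power_vs_p = cor_or_null(m$posthoc_power, m$fisher_p, seed + 4L),
    power_vs_fi = cor_or_null(pow_fi_d$posthoc_power, pow_fi_d$fi, seed + 5L),
    power_vs_rfi = cor_or_null(pow_rfi_d$posthoc_power, pow_rfi_d$rfi, seed + 6L)
  )

  mood_or_null <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    moods_median_test(a, b)
  }

  summary_core <- function(mm) {
    ff <- mm[mm$direction == "fragility", , drop = FALSE]
    rr <- mm[mm$direction == "reverse", , drop = FALSE]
    list(
      fragility = branch_stats(ff, "fi", "fi_quotient_pct"),
      reverse = branch_stats(rr, "rfi", "rfi_quotient_pct")
    )
  }

  out <- list(
    n_publications = length(unique(m$study_id)),
    n_comparisons = nrow(m),
    branches = summary_core(m),
    correlations = correlations,
    mood = list(
      fi_vs_rfi = mood_or_null(frag$fi, rev_$rfi),
      fi_quotient_vs_rfi_quotient = mood_or_null(frag$fi_quotient_pct,
                                                 rev_$rfi_quotient_pct)
    ),
    histograms = list(
      fi = index_histogram(frag$fi),
      fi_quotient_pct = quotient_histogram(frag$fi_quotient_pct),
      rfi = index_histogram(rev_$rfi),
      rfi_quotient_pct = quotient_histogram(rev_$rfi_quotient_pct)
    ),
    sensitivity_1to1 = summary_core(m[m$allocation_ratio == "1:1", , drop = FALSE]),
    n_non_1to1 = sum(m$allocation_ratio != "1:1"),
    settings = list(alpha = alpha, n_boot = as.integer(n_boot),
                    seed = as.integer(seed), rfi_strategy = rfi_strategy,
                    power_correlations = power_correlations),
    metrics = m
  )
  class(out) <- "corpus_summary"
  out
}

# integer-binned counts with cumulative sums (one bin per index value)
index_histogram <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(data.frame(value = integer(0), count = integer(0),
                      cumulative = integer(0)))
  tab <- table(factor(x, levels = 0:max(x)))
  data.frame(value = as.integer(names(tab)), count = as.integer(tab),
             cumulative = cumsum(as.integer(tab)))
}

# 1-percent-wide bins [k, k+1) for quotients
quotient_histogram <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(data.frame(bin_low = numeric(0), bin_high = numeric(0),
                      count = integer(0), cumulative = integer(0)))
  lo <- floor(min(x)); hi <- floor(max(x)) + 1
  cnt <- as.integer(table(cut(x, breaks = lo:hi, right = FALSE,
                              include.lowest = FALSE)))
  data.frame(bin_low = lo:(hi - 1), bin_high = (lo + 1):hi, count = cnt,
             cumulative = cumsum(cnt))
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("Corpus of %d comparisons from %d publication(s)\n",
              x$n_comparisons, x$n_publications))
  pb <- function(lab, b, idx_lab, quo_lab) {
    cat(sprintf("  %s branch: n = %d", lab, b$n))
    if (b$n_sentinel > 0) cat(sprintf(" (%d not attainable)", b$n_sentinel))
    cat("\n")
    if (!is.null(b$index))
      cat(sprintf("    median %s %.4g (IQR %.4g-%.4g); median %s %.4g%% (IQR %.4g-%.4g%%)\n",
                  idx_lab, b$index["median"], b$index["q1"], b$index["q3"],
                  quo_lab, b$quotient["median"], b$quotient["q1"],
                  b$quotient["q3"]))
  }
  pb("fragility", x$branches$fragility, "FI", "quotient")
  pb("reverse", x$branches$reverse, "RFI", "quotient")
  for (nm in names(x$correlations)) {
    cr <- x$correlations[[nm]]
    if (!is.null(cr))
      cat(sprintf("  %s: rho = %.3g [%.3g, %.3g], P = %.4g\n",
                  nm, cr$rho, cr$ci_low, cr$ci_high, cr$p_value))
  }
  if (!is.null(x$mood$fi_vs_rfi))
    cat(sprintf("  Mood FI vs RFI: chi2 = %.4g, P = %.4g\n",
                x$mood$fi_vs_rfi$chi2, x$mood$fi_vs_rfi$p_value))
  invisible(x)
}
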