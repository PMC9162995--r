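# CSV interchange schema for trial-comparison corpora
#
# Required columns: study_id, outcome_label, outcome_tier,
# events_intervention, n_intervention, events_control, n_control.
# Optional: reported_p (the P value printed by the source trial).
# Comma-delimited UTF-8 with a header; "NA" marks missing values. The
# intervention arm is always arm A, fixing the relative-risk orientation
# to treatment over control.

CORPUS_COLUMNS <- c(
  "study_id", "outcome_label", "outcome_tier",
  "events_intervention", "n_intervention", "events_control", "n_control"
)

OUTCOME_TIERS <- c("primary", "secondary", "other")

#' Validate a data frame as a trial-comparison corpus
#'
#' Checks the corpus schema and every row's 2x2 invariants, derives the
#' allocation ratio from the arm sizes (it is never stored
#' independently), and returns a classed corpus. Duplicate
#' `(study_id, outcome_label)` pairs raise a warning but both rows are
#' kept.
#'
#' @param df A data frame with the corpus columns (see Details in
#'   [read_corpus()]).
#' @return A `trial_corpus` data frame with an added `allocation_ratio`
#'   column (`"a:b"` in lowest terms).
#' @export
as_trial_corpus <- function(df) {
  missing_cols <- setdiff(CORPUS_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  count_cols <- c("events_intervention", "n_intervention",
                  "events_control", "n_control")
  for (cc in count_cols) {
    v <- df[[cc]]
    bad <- which(is.na(v) | !is.finite(as.numeric(v)) |
                   as.numeric(v) != round(as.numeric(v)) | as.numeric(v) < 0)
    if (length(bad) > 0L)
      stop(sprintf("column '%s' must hold non-negative integers; bad row(s): %s",
                   cc, paste(bad, collapse = ", ")), call. = FALSE)
    df[[cc]] <- as.integer(v)
  }
  bad <- which(df$events_intervention > df$n_intervention |
                 df$events_control > df$n_control)
  if (length(bad) > 0L)
    stop("events exceed arm size in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(df$n_intervention < 1L | df$n_control < 1L)
  if (length(bad) > 0L)
    stop("arm sizes must be at least 1 in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(!df$outcome_tier %in% OUTCOME_TIERS)
  if (length(bad) > 0L)
    stop("outcome_tier must be one of ", paste(OUTCOME_TIERS, collapse = "/"),
         "; bad row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!"reported_p" %in% names(df)) df$reported_p <- NA_real_
  df$reported_p <- as.numeric(df$reported_p)
  bad <- which(!is.na(df$reported_p) & (df$reported_p <= 0 | df$reported_p > 1))
  if (length(bad) > 0L)
    stop("reported_p outside (0, 1] in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  dup <- duplicated(df[c("study_id", "outcome_label")])
  if (any(dup))
    warning("duplicate (study_id, outcome_label) pairs kept: row(s) ",
            paste(which(dup), collapse = ", "), call. = FALSE)

  df$allocation_ratio <- mapply(ratio_string, df$n_intervention, df$n_control)
  df$study_id <- as.character(df$study_id)
  df$outcome_label <- as.character(df$outcome_label)
  rownames(df) <- NULL
  class(df) <- c("trial_corpus", "data.frame")
  df
}

ratio_string <- function(a, b) {
  g <- gcd(a, b)
  paste0(a %/% g, ":", b %/% g)
}

gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)

#' Read a trial-comparison corpus from CSV
#'
#' Reads and validates a corpus in the package's interchange schema:
#' one row per comparison with columns `study_id`, `outcome_label`,
#' `outcome_tier` (one of primary/secondary/other),
#' `events_intervention`, `n_intervention`, `events_control`,
#' `n_control`, and optionally `reported_p`. Externally extracted tables
#' (e.g. a deposited extraction spreadsheet) are used by renaming their
#' columns onto this schema first.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return A validated `trial_corpus` data frame; row order is preserved
#'   and row numbers in error messages refer to data rows (header
#'   excluded).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_trial_corpus(df)
}

#' Write a corpus (or any corpus-shaped result table) to CSV
#'
#' @param corpus A `trial_corpus` or result data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  utils::write.csv(corpus, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Attach per-comparison metrics to every row of a corpus
#'
#' Runs the full metric block ([comparison_metrics()]) on each
#' comparison: Fisher exact P, S-value, relative risk, fragility and
#' reverse fragility indices and quotients, classification branch, and
#' exact post-hoc power at the observed proportions.
#'
#' @param corpus A `trial_corpus` (see [read_corpus()]).
#' @param alpha Significance level.
#' @param rfi_strategy Passed to [reverse_fragility_index()].
#' @param power_seed Seed for any Monte Carlo power fallback.
#' @return The corpus with metric columns appended, plus `total_n`.
#' @export
corpus_metrics <- function(corpus, alpha = 0.05,
                           rfi_strategy = c("exact", "greedy-toward-separation"),
                           power_seed = 2014L) {
  corpus <- as_trial_corpus(as.data.frame(corpus))
  rfi_strategy <- match.arg(rfi_strategy)
  if (nrow(corpus) == 0L) {
    out <- cbind(corpus, empty_metrics())
    class(out) <- c("trial_corpus", "data.frame")
    return(out)
  }
  metrics <- do.call(rbind, lapply(seq_len(nrow(corpus)), function(i) {
    tab <- fourfold_table(
      corpus$events_intervention[i], corpus$n_intervention[i],
      corpus$events_control[i], corpus$n_control[i]
    )
    comparison_metrics(tab, alpha = alpha, rfi_strategy = rfi_strategy,
                       power_seed = power_seed)
  }))
  out <- cbind(corpus, metrics)
  out$total_n <- out$n_intervention + out$n_control
  class(out) <- c("trial_corpus", "data.frame")
  out
}

empty_metrics <- function() {
  data.frame(
    fisher_p = numeric(0), s_value = numeric(0), rr = numeric(0),
    fi = integer(0), fi_quotient_pct = numeric(0),
    rfi = integer(0), rfi_quotient_pct = numeric(0),
    posthoc_power = numeric(0), power_method = character(0),
    direction = character(0), warnings = character(0),
    total_n = integer(0), stringsAsFactors = FALSE
  )
}

#' Write per-comparison results to CSV
#'
#' Serialises a metrics table from [corpus_metrics()]: input columns plus
#' the metric block, floats at 6 significant digits, unattainable indices
#' as `"NA"`.
#'
#' @param results Output of [corpus_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}
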