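# Report layer: printable metric blocks, JSON summaries, and thin
# wrappers the command-line script dispatches to. Every report embeds
# the package version and the full run configuration (alpha, seeds,
# bootstrap size, RFI strategy, power method), enough to re-run
# bit-identically. P values and quotients print at 4 significant
# digits; S-values at 2 decimals.

#' Compute and print the full metric block for one 2x2 table
#'
#' @param events_a,size_a,events_b,size_b The four cells (events and arm
#'   sizes, intervention first).
#' @param alpha Significance level.
#' @param rfi_strategy Passed to [reverse_fragility_index()].
#' @param quiet Suppress printing.
#' @return The one-row metrics data frame, invisibly.
#' @examples
#' run_compute(0, 5, 5, 5)
#' @export
run_compute <- function(events_a, size_a, events_b, size_b, alpha = 0.05,
                        rfi_strategy = "exact", quiet = FALSE) {
  tab <- fourfold_table(events_a, size_a, events_b, size_b)
  m <- comparison_metrics(tab, alpha = alpha, rfi_strategy = rfi_strategy)
  if (!quiet) {
    cat(sprintf("Comparison %d/%d (intervention) vs %d/%d (control), N = %d\n",
                tab$events_a, tab$size_a, tab$events_b, tab$size_b, total_n(tab)))
    cat(sprintf("  Fisher exact P      %.4g\n", m$fisher_p))
    cat(sprintf("  S-value             %.2f bits\n", m$s_value))
    cat(sprintf("  Relative risk       %s\n",
                if (is.na(m$rr)) "undefined (no control events)" else
                  sprintf("%.4g", m$rr)))
    cat(sprintf("  Branch              %s (alpha = %g)\n", m$direction, alpha))
    fmt_idx <- function(idx, quo) {
      if (is.na(idx)) "not attainable" else
        sprintf("%d (quotient %.4g%%)", idx, quo)
    }
    cat(sprintf("  Fragility index     %s\n", fmt_idx(m$fi, m$fi_quotient_pct)))
    cat(sprintf("  Reverse FI          %s\n", fmt_idx(m$rfi, m$rfi_quotient_pct)))
    cat(sprintf("  Post-hoc power      %.4g (%s)\n", m$posthoc_power,
                m$power_method))
    if (nzchar(m$warnings)) cat(sprintf("  Warnings            %s\n", m$warnings))
  }
  invisible(m)
}

#' Analyze a corpus file and write the JSON summary and metrics CSV
#'
#' Reads a corpus CSV, attaches per-comparison metrics, summarises the
#' corpus, and writes a JSON report (summary, histogram tables, config
#' echo) plus a per-comparison metrics CSV. Deterministic for a fixed
#' seed.
#'
#' @param corpus_path Input corpus CSV.
#' @param json_path Output JSON report (`NULL` to skip).
#' @param csv_path Output per-comparison metrics CSV (`NULL` to skip).
#' @param alpha,n_boot,seed,rfi_strategy,power_correlations Passed to
#'   [summarize_corpus()].
#' @param quiet Suppress the printed summary.
#' @return The `corpus_summary`, invisibly.
#' @export
run_analyze <- function(corpus_path, json_path = NULL, csv_path = NULL,
                        alpha = 0.05, n_boot = 10000L, seed = 2014L,
                        rfi_strategy = "exact",
                        power_correlations = "branch", quiet = FALSE) {
  corpus <- read_corpus(corpus_path)
  s <- summarize_corpus(corpus, alpha = alpha, n_boot = n_boot, seed = seed,
                        rfi_strategy = rfi_strategy,
                        power_correlations = power_correlations)
  if (!is.null(csv_path)) write_results(s$metrics, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary_report(s), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  if (!quiet) print(s)
  invisible(s)
}

#' Convert a corpus summary into a plain serialisable report list
#'
#' @param s A `corpus_summary` from [summarize_corpus()].
#' @return A nested list of plain vectors and data frames, carrying the
#'   package version and the complete run configuration.
#' @export
summary_report <- function(s) {
  stopifnot(inherits(s, "corpus_summary"))
  cor_list <- lapply(s$correlations, function(cr) {
    if (is.null(cr)) return(NULL)
    cr[c("rho", "ci_low", "ci_high", "p_value", "n", "n_boot", "seed")]
  })
  mood_list <- lapply(s$mood, function(mr) {
    if (is.null(mr)) return(NULL)
    list(chi2 = mr$chi2, df = mr$df, p_value = mr$p_value,
         grand_median = mr$grand_median,
         counts = as.data.frame(as.table(mr$counts)))
  })
  branch_list <- function(b) {
    out <- list(n = b$n, n_sentinel = b$n_sentinel)
    if (!is.null(b$index)) {
      out$index <- as.list(b$index)
      out$quotient_pct <- as.list(b$quotient)
    }
    out
  }
  list(
    package = "trialfragility",
    version = as.character(utils::packageVersion("trialfragility")),
    config = s$settings,
    n_publications = s$n_publications,
    n_comparisons = s$n_comparisons,
    branches = lapply(s$branches, branch_list),
    correlations = cor_list,
    mood = mood_list,
    histograms = s$histograms,
    sensitivity_1to1 = lapply(s$sensitivity_1to1, branch_list),
    n_non_1to1 = s$n_non_1to1
  )
}

#' Simulate a synthetic corpus and write it as CSV
#'
#' @param csv_path Output path for the corpus CSV.
#' @param ... Passed to [corpus_config()] (`n_comparisons`, `seed`,
#'   `mixture`, ...).
#' @param quiet Suppress the log line.
#' @return The generated `trial_corpus`, invisibly.
#' @export
run_simulate <- function(csv_path, ..., quiet = FALSE) {
  config <- corpus_config(...)
  corp <- generate_corpus(config)
  write_corpus(corp[, c(CORPUS_COLUMNS, "reported_p")], csv_path)
  if (!quiet) {
    if (config$n_comparisons == 0L)
      message("simulated corpus is empty (n_comparisons = 0); header-only CSV written")
    message(sprintf(
      "wrote %d synthetic comparison(s) to %s (seed %d, mixture %s)",
      nrow(corp), csv_path, config$seed,
      paste(sprintf("%s=%.2f", names(config$mixture), config$mixture),
            collapse = "/")))
  }
  invisible(corp)
}
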