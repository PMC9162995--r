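# Synthetic trial-corpus generator
#
# Emulates a corpus of two-arm trials with dichotomous outcomes the way
# such trials are designed: a control event rate and a minimal
# clinically relevant difference determine the per-arm sample size via
# the standard two-proportion power calculation (80% power, alpha 0.05),
# and observed event counts are independent binomial draws. A mixture of
# null, minimally-powered, and large-effect-small-trial designs produces
# both significant and nonsignificant comparisons over realistic trial
# sizes.

#' Per-arm sample size for comparing two proportions
#'
#' Pooled-variance normal-approximation formula:
#' `n = (z_{1-alpha/2} * sqrt(2 p_bar (1 - p_bar)) +
#' z_{1-beta} * sqrt(p1 (1 - p1) + p2 (1 - p2)))^2 / (p1 - p2)^2`
#' with `p_bar = (p1 + p2) / 2`, rounded up.
#'
#' @param p1,p2 Anticipated event proportions in the two arms; must
#'   differ.
#' @param alpha Two-sided significance level.
#' @param power Target power (1 - beta).
#' @return Patients per arm (integer).
#' @examples
#' required_sample_size(0.2, 0.4) # 82 per arm
#' @export
required_sample_size <- function(p1, p2, alpha = 0.05, power = 0.8) {
  check_alpha(alpha)
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)", call. = FALSE)
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (p1 == p2) stop("p1 and p2 must differ (zero effect needs infinite n)",
                     call. = FALSE)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  pbar <- (p1 + p2) / 2
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  as.integer(ceiling(n))
}

#' Specify one synthetic trial design
#'
#' @param control_rate,treatment_rate True event probabilities of the
#'   control (arm B) and intervention (arm A) arms.
#' @param alpha Significance level the design targets.
#' @param target_power Planned power; used to derive `n_per_group` when
#'   it is not given and the rates differ.
#' @param n_per_group Patients per arm; `NULL` derives it from
#'   [required_sample_size()].
#' @param seed Seed making the subsequent simulation reproducible.
#' @return A `trial_design` list.
#' @export
trial_design <- function(control_rate, treatment_rate, alpha = 0.05,
                         target_power = 0.8, n_per_group = NULL,
                         seed = 2014L) {
  if (any(c(control_rate, treatment_rate) < 0) ||
      any(c(control_rate, treatment_rate) > 1))
    stop("event rates must lie in [0, 1]", call. = FALSE)
  check_alpha(alpha)
  if (is.null(n_per_group)) {
    n_per_group <- required_sample_size(treatment_rate, control_rate,
                                        alpha, target_power)
  }
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stop("n_per_group must be at least 2", call. = FALSE)
  structure(
    list(control_rate = control_rate, treatment_rate = treatment_rate,
         alpha = alpha, target_power = target_power,
         n_per_group = n_per_group, seed = as.integer(seed)),
    class = "trial_design"
  )
}

# independent per-trial RNG stream: a distinct sub-seed per (seed, index)
# keeps any one simulated trial invariant to corpus size and order
trial_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

#' Simulate one trial comparison from a design
#'
#' Event counts are independent binomial draws,
#' `events_a ~ Binomial(n, treatment_rate)` and
#' `events_b ~ Binomial(n, control_rate)`, from a stream seeded by the
#' design seed and the trial index, so a fixed design always yields the
#' same record.
#'
#' @param design A [trial_design()].
#' @param index Trial index within a corpus (part of the sub-seed).
#' @param study_id,outcome_label,outcome_tier Metadata for the record.
#' @param allocation_ratio Arm-size ratio a:1 (control arm scaled);
#'   default 1 (equal arms).
#' @return A one-row data frame in the corpus schema.
#' @export
simulate_trial <- function(design, index = 1L, study_id = "synthetic-1",
                           outcome_label = "outcome", outcome_tier = "primary",
                           allocation_ratio = 1) {
  stopifnot(inherits(design, "trial_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(trial_seed(design$seed, index))
  n_a <- design$n_per_group
  n_b <- max(2L, as.integer(round(design$n_per_group * allocation_ratio)))
  data.frame(
    study_id = study_id,
    outcome_label = outcome_label,
    outcome_tier = outcome_tier,
    events_intervention = stats::rbinom(1L, n_a, design$treatment_rate),
    n_intervention = n_a,
    events_control = stats::rbinom(1L, n_b, design$control_rate),
    n_control = n_b,
    reported_p = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Configure a synthetic corpus
#'
#' The effect mixture governs the kind of design each comparison gets:
#' `null` (identical arm rates), `powered` (a control rate and a
#' clinically relevant difference with per-arm n from the two-proportion
#' formula at the target power, clipped to the size range), and `large`
#' (risk ratio at or below 0.2 in a deliberately small trial, the
#' strong-effect/small-sample pattern of rare-condition surgical
#' trials).
#'
#' @param n_comparisons Number of comparisons to generate.
#' @param size_range Bounds on total N per comparison (default 30-243).
#' @param mixture Named proportions over `c(null, powered, large)`;
#'   must sum to 1.
#' @param tier_mixture Named proportions over
#'   `c(primary, secondary, other)`.
#' @param allocation_ratio Control-to-intervention size ratio (1 = equal
#'   arms).
#' @param alpha,target_power Design parameters for the powered
#'   component.
#' @param seed Corpus seed.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(n_comparisons = 243L,
                          size_range = c(30L, 243L),
                          mixture = c(null = 0.4, powered = 0.4, large = 0.2),
                          tier_mixture = c(primary = 0.35, secondary = 0.40,
                                           other = 0.25),
                          allocation_ratio = 1,
                          alpha = 0.05, target_power = 0.8,
                          seed = 2014L) {
  if (n_comparisons < 0L) stop("n_comparisons must be non-negative", call. = FALSE)
  if (length(size_range) != 2L || any(size_range < 4L) ||
      size_range[1L] > size_range[2L])
    stop("size_range must be increasing total-N bounds of at least 4", call. = FALSE)
  if (is.null(names(mixture)) ||
      !setequal(names(mixture), c("null", "powered", "large")))
    stop("mixture must be named over null/powered/large", call. = FALSE)
  if (any(mixture < 0) || sum(mixture) == 0)
    stop("mixture proportions must be non-negative and not all zero", call. = FALSE)
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1", call. = FALSE)
  if (abs(sum(tier_mixture) - 1) > 1e-8 ||
      !setequal(names(tier_mixture), c("primary", "secondary", "other")))
    stop("tier_mixture must be named over primary/secondary/other and sum to 1",
         call. = FALSE)
  check_alpha(alpha)
  structure(
    list(n_comparisons = as.integer(n_comparisons),
         size_range = as.integer(size_range),
         mixture = mixture[c("null", "powered", "large")],
         tier_mixture = tier_mixture[c("primary", "secondary", "other")],
         allocation_ratio = allocation_ratio,
         alpha = alpha, target_power = target_power,
         seed = as.integer(seed)),
    class = "corpus_config"
  )
}

#' Generate a reproducible synthetic corpus of trial comparisons
#'
#' Draws one design per comparison from the configured effect mixture,
#' simulates binomial event counts, and returns a validated corpus. The
#' corpus is byte-identical for identical configurations (each
#' comparison has its own sub-seed derived from the corpus seed and its
#' index).
#'
#' @param config A [corpus_config()].
#' @return A `trial_corpus` with `n_comparisons` rows.
#' @examples
#' corp <- generate_corpus(corpus_config(n_comparisons = 10, seed = 1))
#' @export
generate_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  lo <- config$size_range[1L]; hi <- config$size_range[2L]
  # per-group bounds for a 1:1 trial within the total-N range
  g_lo <- max(2L, as.integer(ceiling(lo / 2)))
  g_hi <- max(g_lo, as.integer(floor(hi / 2)))
  rows <- lapply(seq_len(config$n_comparisons), function(i) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    # even sub-index seeds the design draws, odd one the outcome draws
    # inside simulate_trial, so the two streams never collide
    set.seed(trial_seed(config$seed, 2L * i))
    comp <- sample(names(config$mixture), 1L, prob = config$mixture)
    tier <- sample(names(config$tier_mixture), 1L, prob = config$tier_mixture)
    if (comp == "null") {
      rate_b <- stats::runif(1L, 0.10, 0.50)
      rate_a <- rate_b
      n <- sample(g_lo:g_hi, 1L)
    } else if (comp == "powered") {
      rate_b <- stats::runif(1L, 0.30, 0.65)
      rate_a <- max(0.02, rate_b - stats::runif(1L, 0.18, 0.35))
      n <- min(max(required_sample_size(rate_a, rate_b, config$alpha,
                                        config$target_power), g_lo), g_hi)
    } else {
      rate_b <- stats::runif(1L, 0.50, 0.90)
      rate_a <- stats::runif(1L, 0.05, 0.20) * rate_b
      n <- sample(g_lo:min(g_hi, max(g_lo, 40L)), 1L)
    }
    design <- trial_design(rate_b, rate_a, alpha = config$alpha,
                           target_power = config$target_power,
                           n_per_group = n, seed = config$seed)
    rec <- simulate_trial(design, index = 2L * i + 1L,
                          study_id = sprintf("synthetic-%03d", i),
                          outcome_label = paste0(comp, "-effect outcome"),
                          outcome_tier = tier,
                          allocation_ratio = config$allocation_ratio)
    list(rec = rec,
         des = data.frame(component = comp, rate_a = rate_a, rate_b = rate_b,
                          n_per_group = n, stringsAsFactors = FALSE))
  })
  df <- if (length(rows) == 0L) {
    data.frame(study_id = character(0), outcome_label = character(0),
               outcome_tier = character(0), events_intervention = integer(0),
               n_intervention = integer(0), events_control = integer(0),
               n_control = integer(0), reported_p = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(rows, `[[`, "rec"))
  }
  corp <- as_trial_corpus(df)
  attr(corp, "config") <- config
  # true generating parameters per comparison, for parameter-recovery
  # checks; not part of the CSV schema and dropped on write
  attr(corp, "designs") <- if (length(rows) == 0L) NULL else
    do.call(rbind, lapply(rows, `[[`, "des"))
  corp
}
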