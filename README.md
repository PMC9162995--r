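# trialfragility

Fragility metrics for two-arm trials with dichotomous outcomes, and the
corpus-level statistics used in meta-research on them.

## The problem

The *fragility index* (FI) of a statistically significant two-arm
comparison is the smallest number of patients in the arm with fewer
events whose outcome must be switched from non-event to event before the
two-sided Fisher exact P value rises to or above α. Its counterpart for
nonsignificant comparisons, the *reverse fragility index* (RFI), is the
smallest number of single-patient outcome switches (in either arm, arm
sizes fixed) that drives the P value below α. Both are often normalised
by the trial's total sample size and expressed as a percent — the
*fragility quotient*. Because both indices are deterministic functions of
the same 2×2 table as the P value itself, they track the P value closely;
this package computes every quantity needed to study that relationship:

- the two-sided conditional exact (Fisher) P value, by the
  minimum-likelihood rule: conditioning on both margins, the
  intervention-arm event count X is hypergeometric, and
  P = Σ Pr(X = x) over all x with Pr(X = x) ≤ Pr(X = x_obs);
- the Shannon **S-value** S = −log₂(P), the information against the test
  hypothesis in bits (S = 5 is as surprising as five heads in five fair
  coin tosses);
- **FI**, **RFI** (exact grid minimum or a greedy stepwise variant), and
  their quotients 100·index/N;
- the **relative risk** (events_a/size_a)/(events_b/size_b), intervention
  over control;
- exact **post-hoc power** of the two-sided Fisher test at the observed
  arm proportions, by full enumeration of both binomial outcome
  distributions: power = Σₓₐ Σₓᵦ B(xₐ; nₐ, pₐ)·B(xᵦ; nᵦ, pᵦ)·1[P(xₐ,xᵦ) < α];
- corpus summaries: per-branch medians with type-7 interquartile ranges,
  Spearman correlations with 10,000-resample bootstrap percentile
  confidence intervals, Mood's median test (χ² on counts above/at-or-below
  the pooled grand median, df = 1), histogram/cumulative tables, and a
  sensitivity variant dropping non-1:1-allocated comparisons;
- a seeded synthetic corpus generator whose designs come from the
  standard pooled-variance two-proportion sample-size formula at 80%
  power and α = 0.05, mixed with null and large-effect/small-trial
  designs.

It is aimed at methodologists examining what fragility indices do and do
not add over the P value, and at readers who want to recompute the
metrics for individual trials.

## Worked example

Two hypothetical trials with (almost) the same P value but very different
effects — 1/100 vs 9/100 events against 200/4000 vs 250/4000:

```r
library(trialfragility)
run_compute(1, 100, 9, 100)
#> Comparison 1/100 (intervention) vs 9/100 (control), N = 200
#>   Fisher exact P      0.01849
#>   S-value             5.76 bits
#>   Relative risk       0.1111
#>   Branch              fragility (alpha = 0.05)
#>   Fragility index     1 (quotient 0.5%)
#>   Reverse FI          0 (quotient 0%)
#>   Post-hoc power      0.6775 (enumeration)
```

The small trial has a relative risk of 0.11 — a strong effect — yet a
fragility index of 1: a single switched outcome makes it nonsignificant
(P becomes 0.058). The large trial shows RR 0.8 at the same rounded
P = 0.02 but carries a much larger FI, illustrating how the index
penalises small trials irrespective of clinical relevance. A full corpus
analysis runs from a CSV (schema: `study_id, outcome_label, outcome_tier,
events_intervention, n_intervention, events_control, n_control
[, reported_p]`):

```r
run_simulate("corpus.csv", n_comparisons = 243, seed = 2014)
run_analyze("corpus.csv", json_path = "report.json", csv_path = "metrics.csv")
```

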