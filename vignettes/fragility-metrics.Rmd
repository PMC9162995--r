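---
title: "Fragility metrics for 2x2 trial comparisons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragility metrics for 2x2 trial comparisons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialfragility)
```

## The model

Every comparison is a 2×2 table: events and arm sizes for an
intervention arm A and a control arm B. Conditional on both margins, the
intervention-arm event count is hypergeometric, and the two-sided exact
P value is the minimum-likelihood sum — all point probabilities no
greater than the observed one (with a 10⁻⁷ relative tolerance for
floating ties, the convention of `stats::fisher.test`, with which the
implementation agrees to machine precision on exhaustive small grids).

The **fragility index** of a significant table is produced by a
deterministic walk: repeatedly convert one non-event to an event in the
arm currently holding fewer events (ties broken toward the smaller arm,
then arm A), recomputing P after each conversion, and stop the first
time P ≥ α. The walk's path does not depend on α, only the stopping
point does; a consequence worth knowing is that the index is
non-decreasing in α. If the chosen arm runs out of non-events the walk
continues in the other arm and flags the result; if both arms saturate
the index is reported as not attainable (`NA`).

The **reverse fragility index** of a nonsignificant table is defined
here as the exact minimum number of single-patient outcome switches
reaching any significant table — the minimum L1 distance
|Δeventsₐ| + |Δevents_b| over the (nₐ+1)×(n_b+1) grid of attainable
tables, found by exhaustive scan. Verbal definitions of the reverse
index in the literature describe a stepwise process whose direction is
ambiguous; the exact minimum is well defined, cheap at trial scale
(the grid for a 243-patient comparison has ~15,000 cells), and lower
bounds every stepwise variant. For comparability with stepwise
calculators a `"greedy-toward-separation"` strategy is provided: take,
one at a time, the single switch that most decreases P, stopping at the
first significant table. The test suite confirms the greedy count never
beats the exact minimum.

Both indices are normalised as **quotients**, 100·index/N, in percent.

**Classification convention.** A comparison enters the fragility branch
exactly when its Fisher P is below α, regardless of what test the
source trial reported; a reported-significant comparison whose Fisher P
lands at or above α gets FI = 0 rather than being excluded. This is the
only convention under which the fragility branch's interquartile range
can reach down to 0.

**Post-hoc power** is the exact power of the two-sided Fisher test with
the observed proportions taken as true rates: the total binomial
probability of all outcome pairs that would be significant. Full
enumeration is used up to 4×10⁶ outcome pairs (every trial size in
scope); beyond that a seeded Monte Carlo estimate (default 10⁵ draws,
seed 2014) is substituted and the method is recorded in the result.
Post-hoc power is a monotone transform of the evidence in the table, so
it correlates strongly and negatively with P — one of the structural
facts the corpus statistics exhibit.

**S-values.** P values are also reported as surprisals, S = −log₂(P):
bits of information against the test hypothesis, with the fair-coin
interpretation that S = 5 is as surprising as five heads in five
tosses. The S-value makes visible how wide a range of evidence a single
fragility index value lumps together: the same FI of 1 can arise from
P = 0.039 (4.68 bits) and from P = 0.003 (8.38 bits).

## Corpus statistics

`summarize_corpus()` computes the results battery over a validated
corpus: branch sizes; per-branch medians and interquartile ranges of
index and quotient (type-7 linear interpolation, so integer indices can
have fractional medians such as 1.5); Spearman correlations of each
index with its branch's P values and total sample sizes, of power with
P over all comparisons, and of power with each index over that index's
branch (a `power_correlations = "pooled"` switch pools the index–power
pairs instead; the branch scoping is the default because each index is
only defined meaningfully on its own branch); Mood's median test
between the FI and RFI distributions and between the quotient
distributions; histogram and cumulative-count tables (unit bins for
indices, 1-percentage-point bins for quotients); and a sensitivity
variant restricted to 1:1-allocated comparisons, which equals the full
summary whenever every comparison is 1:1.

Bootstrap confidence intervals for Spearman's ρ are percentile
intervals over paired (case) resamples, default 10,000 repetitions,
seeded (default 2014) and echoed in every result; the P value uses the
t approximation with n−2 degrees of freedom. Mood's test classifies
values as above versus at-or-below the pooled grand median (ties low)
and applies the Pearson χ² without continuity correction, df = 1; other
tie rules exist, and with heavily tied integer indices the statistic is
sensitive to that choice, which is why the convention is fixed and
documented here. Comparisons, not publications, are the analysis unit;
no clustering adjustment is applied. Unattainable indices are excluded
from medians and correlations and counted separately.

## The synthetic generator

`generate_corpus()` emulates the statistical structure the analysis
assumes, so the whole pipeline is testable without any particular
extraction dataset. Each comparison draws a design from a three-part
mixture (defaults 0.4/0.4/0.2):

- **null** — equal arm rates, drawn uniformly from 0.10–0.50, with
  per-arm size uniform over the allowed range;
- **minimally powered** — a control rate from 0.30–0.65 and an absolute
  risk reduction of 0.18–0.35, with the per-arm size from the
  pooled-variance two-proportion formula at 80% power and α = 0.05
  (`required_sample_size()`), clipped into the size range. This mirrors
  how such trials are actually sized, and it is the reason corpora are
  dominated by P values just below the threshold and small fragility
  indices;
- **large effect** — risk ratio 0.05–0.20 against a control rate of
  0.50–0.90 in a deliberately small trial (≤ 40 per arm), the
  strong-effect/rare-condition pattern.

Event counts are independent binomial draws. Total N is bounded to
30–243 by default and allocation is 1:1 (a ratio parameter covers
unequal arms). Every comparison owns a sub-seed derived from the corpus
seed and its index (even offsets for design draws, odd for outcome
draws), so corpora are byte-identical under a fixed configuration and
single trials are reproducible in isolation. The true generating rates
are attached as a `designs` attribute for parameter-recovery checks.

The mixture proportions and rate ranges are modelling choices, not
estimates from any particular corpus: they are set to produce both
branches in comparable numbers over realistic trial sizes, which is
what exercising every corpus statistic requires. Consequently the
generator reproduces the *qualitative* structure — the sign pattern
FI∼P negative, RFI∼P positive, power∼P negative, power∼FI positive,
stable across seeds — but not the exact medians or ρ values of any
observed corpus; those depend on the joint distribution of effects and
sample sizes in the real literature, which only the extracted data
determine. Real corpora also carry features the generator omits:
within-publication correlation of comparisons, non-binomial outcome
dependence, selective reporting.

## Numerical choices

- **Knife-edge significance.** Exact P values are rationals and can
  equal α exactly (the table 2/4 vs 0/12 has P = 1/20). Floating
  summation can land either side of α and make two correct
  implementations disagree. Every significance decision therefore uses
  `p < α·(1 − 10⁻⁹)`; at trial-scale tables any achievable P other than
  α itself is orders of magnitude further from α than the guard, so
  only exact ties are affected, and they classify as nonsignificant —
  the answer strict comparison on the exact rational gives.
- **Grid computation.** P values for a full outcome grid are computed
  one anti-diagonal (fixed event total) at a time; sorting each
  diagonal's point probabilities once turns all minimum-likelihood
  sums into cumulative-sum lookups.
- **Degenerate inputs.** A table with no events (or all events) in both
  arms has P = 1, FI = 0, and its RFI comes from the same grid search
  as any other table; two-patient arms where no grid cell is
  significant return the not-attainable sentinel.
- **Precision conventions.** Reports print P values and quotients at 4
  significant digits and S-values at 2 decimals; CSV output carries 6
  significant digits; sentinels serialise as `NA`.

## Problem sizes in the checks

The test suite verifies the index algorithms against two independent
oracles — a stepwise replay and a brute-force grid scan, both built on
`stats::fisher.test` — exhaustively over all 8,100 tables with up to 12
patients per arm, and property-based over random larger tables.
Enumerated power is checked against a 10⁶-draw Monte Carlo estimate.
Corpus-level structure is checked on 243-comparison synthetic corpora
across 20 seeds; corpus statistics in the faster-running examples use
smaller corpora and bootstrap sizes, with the full defaults (10,000
resamples) exercised through the same code path.

## Limitations

Only dichotomous outcomes summarised as 2×2 tables are supported —
continuous and time-to-event outcomes are out of scope, as are mid-P or
unconditional (Barnard/Boschloo) tests, continuity-corrected relative
risks, and meta-analytic pooling. The fragility index itself is, by
construction, a transform of the exact P value; the package's purpose
is to make that relationship measurable, not to endorse the metric.
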