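---
title: "Methods: crossover MRMC analysis and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover MRMC analysis and the synthetic cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readerstudy)
```

This vignette is the package's own account of its statistical methods: the
study design it analyzes, the estimators and tests it implements, the
generative model behind the synthetic cohorts, and the numerical and design
choices that were genuinely open.

## The design

A two-period crossover MRMC study: R readers (default 8, of whom 6 are
board-certified radiologists, plus a neurosurgeon and a resident) each label
the same N cases (default 115, 50% prevalence) twice — once with and once
without an assistance condition — separated by a washout (default 14 days)
to limit recall. Readers are split randomly and equally into two groups that
take the conditions in opposite order; within each group, half read the
cases in a fixed random order and half in its exact reversal. Each read is a
single binary call ("at least one clinically significant lesion", defined as
diameter > 3 mm), logged with an entry timestamp.

Because every reader reads every case under both conditions, readers serve
as their own controls and the reader is the natural unit for inference about
the condition effect.

## Estimators and tests

**Pooled metrics and Wilson intervals.** Per-reader confusion counts are
summed across readers ("microaveraging") and metrics are computed on the
pooled counts, so pooled sensitivity is ΣTP/(ΣTP+ΣFN) over all R·N reads.
Uncertainty uses the Wilson score interval, which inverts the score test and
behaves well near 0 and 1 — relevant here because specificities around
0.96–0.99 sit close to the boundary, where Wald intervals overshoot. The
normal quantile is used at full precision (1.959964... at 95%), not rounded
to 1.96; both choices reproduce the same 3-decimal intervals at these sample
sizes, but the exact quantile is the defined statistic. Metrics with a zero
denominator raise an error rather than returning `NaN`: a silent `NaN` would
propagate into the paired t tests.

**Paired one-tailed t tests.** For each metric the per-reader differences
d_r = (augmented − unaugmented) give t = mean(d)/(sd(d)/√R) on R−1 df, with
the upper tail as the alternative ("assistance improves the metric"; for
time, the lower tail). With R = 8 the t distribution is used exactly, never
a normal approximation. The interval reported next to the one-tailed p is
the conventional two-sided 95% t interval for the mean difference — the
presentation used in study tables, where a symmetric CI accompanies a
directional p. The same machinery runs on the radiologist subset (df = 5 at
the default roster) as a robustness analysis against the inclusion of the
resident and neurosurgeon.

**Time to diagnosis.** Readers enter one label per case, so per-case times
are the consecutive differences of entry timestamps in reading order: N
entries yield N−1 durations (the first case has no predecessor; with 115
cases, 114 durations per reader-session). The phrase "time between
consecutive entries" could also be read as a difference of session-mean
entry times, but only per-case durations give the trimming rule something to
operate on, so consecutive differences are the implemented definition. The
5 longest and 5 shortest durations per reader-session are removed before any
summary (k is configurable via `trim_k`); trimming happens per reader-session
*before* pooling across readers, since interruptions are reader-level
events. Ties at the trim cut are broken by stable original order. Summaries
are means with two-sided 95% Student-t intervals.

**Exact Fleiss κ.** "Exact" is Conger's multi-rater form: observed agreement
is the proportion of concordant rater pairs, and expected agreement uses
*rater-specific* marginal rates averaged over all rater pairs,
P_e = 2/(R(R−1)) Σ_{r<r'} Σ_j p_rj p_r'j. This is the statistic that
agreement software ships under the name "exact Fleiss kappa", and for R = 2
it reduces to Cohen's κ. The classic Fleiss variant (pooled marginals,
P_e = Σ p̄_j²) is available behind `exact = FALSE` for comparison, since the
name alone does not pin the variant down. If every rater assigns the same
single category to every case, P_e = 1 and κ is undefined; this raises an
explicit degeneracy error.

**Permutation test for the κ difference.** Under the null that the session
labels are exchangeable, each permutation swaps — independently per case
with probability ½ — that case's complete row of R labels between the two
session matrices, then recomputes the κ difference; B = 10 000 by default.
Swapping whole case rows preserves the within-case inter-rater correlation,
which is the correlation structure the statistic is about; a cell-level swap
(each reader-case label independently) is exposed as `unit = "cell"` because
the design description "a random subset of the test set was relabelled"
admits either reading, but case-level is the documented primary. The p value
is the proportion of permuted differences *strictly greater* than the
observed one; this matches the test's definition but can return exactly 0
(two identical matrices warn about the degenerate null), so a smoothed
(count+1)/(B+1) estimator is available for users who need guaranteed-positive
p values.

**Multiplicity.** A full run registers eight hypotheses — sensitivity,
specificity and accuracy for all readers and for radiologists, the time
decrease, and the κ increase — and adjusts with Benjamini–Hochberg (step-up,
`stats::p.adjust`). The family roster is explicit in the config and logged
in the manifest, never implicit: adjusted p values are only interpretable
relative to a declared family (m = 8 here).

## The synthetic cohort generator

The generator's job is to produce data with the statistical structure the
analysis assumes, at the design's scale, with known ground truth — so
calibration, power and type-I error of the whole pipeline are checkable.

**Truth tables.** The positive count is deterministic,
round-half-up(N·prevalence) — 58 of 115 at 50% — mirroring stratified
test-set construction (a Bernoulli draw would add irrelevant prevalence
noise). Positive cases draw a largest-lesion diameter from four strata
(3–7, 7–12, 12–24, ≥24 mm) with weights 148:108:61:11, the size distribution
of the aneurysm cohort the defaults emulate, uniform within a stratum; a
second lesion occurs with probability 20/328.

**Annotations: probit latent-trait model.** Case c carries a latent
difficulty z_c ~ N(0,1) shared by all readers and both sessions — the same
hard cases are missed in both arms, which is what makes a crossover on
identical cases informative. Reader r has propensities a_r ~ N(a0, σ_a²)
and b_r ~ N(b0, σ_b²), fixed across sessions. With aug ∈ {0,1}:

- positive case: P(label 1) = Φ(a_r + δ_sens·aug − τ·z_c)
- negative case: P(label 1) = Φ(b_r + δ_fp·aug + τ·z_c), δ_fp ≤ 0

Averaging Φ(a_r − τ z_c) over both Gaussians gives the closed form
Φ(a0/√(1+τ²+σ_a²)), so the generator solves for its intercepts and shifts
directly from the configured target rates:
a0 = Φ⁻¹(target)·√(1+τ²+σ_a²), and likewise for the shifts. The configured
session targets (defaults 0.831 → 0.890 sensitivity, 0.960 → 0.975
specificity) are therefore reproduced *in expectation, exactly*; simulation
error is purely Monte-Carlo. This probit structure was chosen as the
simplest generative model that yields both reader heterogeneity and
case-driven inter-reader correlation; no generative model is implied by the
analysis itself.

**Free parameters and their defaults.** τ (case coupling, probit scale)
defaults to 1.6 with reader SDs σ_a = σ_b = 0.3: at these values the
simulated exact Fleiss κ sits near 0.80 without and 0.86 with assistance,
the agreement level reported for the study the defaults emulate, and the
per-reader spread is qualitatively consistent with published per-reader
ranges. Neither parameter is identified by the pooled targets — they were
fixed once from the published agreement level and are not adjusted
thereafter. Agreement is monotone in τ (a tested property), so users can
explore other regimes.

**Reading times.** Durations are lognormal with configured median 50 s and
mean 57 s (hence meanlog = log 50, sdlog = √(2·log(57/50)) ≈ 0.512). With
probability 0.02 a duration gains a Uniform(300, 1200) s interruption — a
two-component mixture that gives the 5/5 trimming rule something real to
remove. Entry timestamps are cumulative sums along each reader's case order.
Note the *trimmed* mean of this skewed mixture is slightly below the raw
lognormal mean (≈56.3 s vs 57 s at the default shape): the tests therefore
check the trimmed statistic against a brute-force oracle of the trimmed
sampling distribution, and the raw mean against its configured value.
No session effect on time is simulated by default: the emulated study found
no significant time change.

**Toy segmentation volumes.** For pipeline tests of the binarization rule, a
positive case's volume is sub-threshold background noise (uniform < 0.45)
plus one spherical blob with peak 0.95 whose radius tracks the lesion
diameter; a negative case is background only. The rule "positive iff at
least one voxel strictly exceeds 0.5" recovers the truth by construction.
The threshold inequality is strict because the emulated display rule is
"probability greater than 0.5"; a "≥" dialect changes only the
measure-zero boundary case, but the choice is documented and tested.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: actual CTA appearance or CNN behaviour (volumes
are geometric toys), session order effects and washout failure (no carryover
is simulated), reader fatigue or learning, non-stationary reading speed, and
per-case difficulty that differs between positive detection and negative
dismissal beyond a single shared latent. Conclusions about the *pipeline*
(calibration, error control, power at the design size) transfer; conclusions
about any particular clinical dataset do not.

## Determinism and seeds

A single master seed in the config drives everything; substreams use fixed
offsets (+1 truth, +2 crossover, +3 annotations, +4 times, +5 permutation),
so any stage can be re-run in isolation and the permutation stream is
decoupled from the simulator's. Reruns at the same config and seed are
byte-identical in all machine-readable outputs; for that reason the run
manifest records seeds, B, the BH family and a config hash, but no
wall-clock timestamps.

## Problem sizes used by the test suite

The suite checks the exact-κ implementation against a brute-force pairwise
oracle on 1000 random matrices (2–6 raters, 3–20 cases) at 1e-12;
permutation p-value uniformity on 200 exchangeable simulated studies at the
full 8 × 115 design with B = 200 per study (Kolmogorov–Smirnov at α = 0.01);
effect recovery and test power over 500 simulated studies and type-I error
over 1000 null studies; and generator calibration over 60 replicate studies.
These sizes give Monte-Carlo standard errors comfortably below the
tolerances being asserted while keeping the default test run fast.

## Known limitations

- Binary per-examination labels only: no per-lesion (FROC) scoring, no
  ROC/AUC MRMC machinery (Obuchowski–Rockette, DBM), no ordinal or weighted
  κ. The analyzed task is a binary call, and the implemented statistics are
  the ones defined for it.
- The paired t tests treat cases as fixed: inference generalizes over
  readers for this case set, which is the estimand of the emulated design,
  not a random-cases generalization.
- The permutation test assumes session exchangeability under the null;
  genuine order effects would violate it and are not modelled.
- Missing annotations are a hard error by policy. The emulated design has
  complete data; imputation would silently change every downstream
  denominator.
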