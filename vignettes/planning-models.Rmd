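---
title: "Ordinal planning models for previewed click sequences: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal planning models for previewed click sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precrastr)
```

## The task and the four models

A participant watches a self-paced preview of six numbered targets in which
one target may be withheld, ends the preview when ready, and then clicks
the six targets in numerical order. The withheld target (condition
`m = 1..6`) is revealed when the preview ends. The data per trial are the
preview time and the six inter-click times `T1..T6`.

Each planning account assigns every (condition, response) cell an ordinal
preparation level: 1 — the response was fully specified before execution
began; 2 — partly specified, finished concurrently with the first click;
3 — not specified at all. The four 6×6 level matrices differ in *when* the
initially uncertain response gets specified:

- **Slow procrastination** — responses are prepared during the preview only
  up to the uncertain one; everything from the uncertain response onward is
  specified one-by-one during execution (row `m`: level 1 before `m`,
  level 3 from `m` on). Mean theoretical cost 13 steps.
- **Fast procrastination** — all certain responses are prepared in the
  preview; only the uncertain response is specified, at its own position,
  during execution (level 3 on the diagonal). 8 steps.
- **Slow pre-crastination** — the uncertain response is specified
  immediately after the preview ends, before the first click, so only the
  first response is slow (level 3 in column 1, every row). 8 steps.
- **Fast pre-crastination** — as above when target 1 itself is uncertain
  (level 3 at cell (1,1)); otherwise specification of the uncertain
  response overlaps with the first click, making the first response only
  partly delayed (level 2 in column 1, rows 2–6). 43/6 ≈ 7.17 steps, the
  fastest account, and the only one that uses level 2 — hence its third
  free parameter.

Given subject-level times `t1 ≤ t2 ≤ t3`, a model predicts cell means
`T(m, j) = t[L(m, j)]`. The model makes no distributional claim beyond
these cell means; we treat within-cell variation as exchangeable noise.

## Fitting

Per subject, the objective is the sum of squared differences between the
36 observed cell means and the predicted times. Because the predictor is
piecewise constant over level groups, the unconstrained optimum per level
is the mean of that level's cells, and the order constraint is enforced by
pooled adjacent violators (PAVA): adjacent level groups that violate the
ordering are merged and share their weighted mean. With at most three
groups this is exact and closed-form; the test suite checks it against an
exhaustive 10⁻³ s grid search on a thousand random cell matrices.

Numerical choices, made once:

- **Weak ordering** (`t1 ≤ t2 ≤ t3`). Ties are legal outcomes — with weak
  ordering the three-parameter model can always reproduce a two-parameter
  fit by setting `t2 = t3`, which keeps the model comparison conservative
  and well defined.
- **Unweighted cells by default.** The objective weighs the 36 cell means
  equally, matching an analysis phrased in terms of "the 36 mean observed
  times"; a count-weighted switch (`weighted = TRUE`) exists because cells
  can lose observations to the outlier filter.
- **Adjusted R²** uses the Ezekiel formula
  `1 − (SSE/SST)·(n−1)/(n−p−1)` with `n` = number of defined cells
  (36 in the complete design) and `p` = 2 or 3. `SST` is computed over the
  same defined cells as `SSE`, so competing models are scored on identical
  data. Cells with no surviving observations are excluded from both, and a
  fit with fewer than `p + 2` cells flags its adjusted R² unreliable.
- **Monte Carlo engine.** As a cross-check of the exact solver and a
  replication of random-search estimation, `fit_monte_carlo()` draws level
  tuples uniformly on `[0, max cell mean]`, sorts each draw ascending, and
  keeps the lowest-SSE candidate; 10⁴ draws by default, seeded, and the
  caller's RNG stream is restored afterwards. Its SSE is bounded below by
  the exact engine's. The convergence check (SSE within 1% of exact at 10⁵
  draws) uses a fixture with cell noise of SD 0.15 s: the uniform proposal
  reaches a 1% relative-SSE neighbourhood with comfortable probability at
  that noise, whereas at much smaller noise the target ellipsoid shrinks
  like σ³ and no plain uniform search of that size can be expected to land
  in it — a property of the search scheme, not of the solver it checks.
- **Ties in selection.** Subjects whose best adjusted R² is shared by two
  models are recorded as `TIE`, never silently assigned.

## The synthetic cohort

`simulate_experiment()` generates what the analysis assumes and nothing
more: per subject, a seeded random permutation of ten repetitions of each
withheld-target condition (60 trials, the first six treated as practice by
the preprocessing, not by the generator); response times equal to the
generating model's predicted cell mean plus additive Gaussian noise,
floored at 0.05 s; rare outliers replacing a time with a uniform draw on
(3, 10] s; and preview times that are Gaussian around a subject-level base,
reduced when target 1 is the withheld one. A global seed drives per-subject
substreams, so enlarging a cohort never reshuffles existing subjects, and
identical configurations give byte-identical trial CSVs.

Defaults were chosen once to echo group means typical of this task: level
times centred at (0.67, 0.80, 1.20) s with between-subject SDs of about
0.08–0.10 s, trial noise SD 0.12 s, outlier probability 0.005 (so > 99% of
observations survive the 3-s cutoff), preview base 3.0 s (SD 1.4 s across
trials) with a 0.4-s reduction when target 1 is missing, and 4.1 s in
full-preview mode. Outliers are drawn strictly above the cutoff so the
filter removes exactly the injected contamination, which makes retention
accounting exact in tests.

What the generator does *not* emulate: spatial layout and cursor
trajectories, error clicks (no error-rate estimate exists to calibrate
one), sequential dependencies between trials, non-Gaussian response-time
skew, and learning across the session beyond the practice-trial
convention. Passing recovery tests therefore show that the estimation and
selection machinery identifies the generating structure under the stated
noise model — not that real data satisfy that noise model.

## Preprocessing

Trials 1–6 are practice and dropped by index. The 3-s cutoff then removes
*individual* response-time observations, not whole trials — dropping a
whole trial because one late click lapsed would discard five valid
observations; the whole-trial variant is available via `drop = "trial"`.
Cell means are arithmetic means of surviving observations; empty cells are
`NA` with a warning and are excluded from fitting. The filter report
includes the Pearson correlation between filtered and unfiltered grand
condition×response means, a check that filtering alters scale, not
pattern.

## Group statistics

Per-subject summaries are computed first (first-response time with target 1
withheld vs shown, the mean of responses 2–6, preview means by condition),
then contrasted across subjects with a paired one-tailed t (df = n−1) —
the only reading consistent with subject-level degrees of freedom. The
repeated-measures effect size is `d_rm = (M_diff / SD_diff)·√(2(1−r))`
with `r` the paired correlation; `d_pooled` accompanies Welch's test.
Winner counts get the exact binomial point mass at chance 1/4 (log-space
`lchoose` arithmetic), with the upper tail reported alongside: the point
mass is what published winner-count probabilities of this design equal
digit-for-digit, and the tail is the conventional test quantity, so both
are shown. Full-preview cohorts get a one-way repeated-measures ANOVA over
the six responses (`aov` with a subject error stratum; df 5 and 5(n−1))
with all 15 Bonferroni-multiplied pairwise paired t tests. Welch's t
accepts raw samples or (mean, SD, n) summaries; note that t and df
recomputed from rounded published summaries can differ noticeably from
originally reported values, so summary-based results are labelled as such.
The a-priori sample-size routine iterates n over the noncentral t
distribution until the target power is reached; at d = 0.5, two-sided
α = .05 and 80% power it returns 34.

## Validation scale and known limitations

The test suite's heavier simulations use sizes chosen to keep the whole
suite under half a minute while leaving sampling error far smaller than the
margins being asserted: 100 subjects per generating model for the recovery
confusion matrix, 200 subjects for parameter recovery at 0.05-s noise,
1,000 random fixtures against the grid-search oracle, 500 null datasets of
200 subjects for ANOVA type-I calibration.

Two limitations are worth stating plainly:

- **Adjusted-R² selection over-selects the nesting model.** With weak
  ordering, fast pre-crastination reproduces any slow pre-crastination fit
  and refines its column-1 partition. For cohorts *generated* under slow
  pre-crastination, the three-parameter model wins whenever the one-df
  between-subgroup sum of squares exceeds roughly SSE/33 — a scale-free
  event with probability near 0.15 regardless of noise level, repetition
  count, or cohort size (both sides of the comparison scale with σ²).
  Recovery simulations accordingly put that diagonal at about 0.82–0.89,
  not higher; the other three models recover at 0.97–1.00. This is a
  property of adjusted-R² model comparison itself, and the package reports
  it rather than papering over it; an information criterion with a stiffer
  penalty, or a tie margin, would trade it against sensitivity to genuine
  partial preparation.
- **The generator is an idealisation.** Conclusions about real cohorts
  require the real trial records; the package reads external trial CSVs
  via a user-supplied column mapping (`read_external_trials()`), and every
  analysis stage downstream of the trial table is identical for simulated
  and loaded data.
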