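---
title: "Predicting a cognitive-reserve residual from connectome edges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting a cognitive-reserve residual from connectome edges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cpmreserve implements connectome-based predictive modelling (CPM) of a
residual measure of cognitive reserve, end to end: from node time series
or precomputed connectivity matrices, through motion-based quality
control, a residual reserve score, mass-univariate edge selection and
cross-validated network-strength models, to validity testing,
selected-edge anatomy, and cross-dataset application. This vignette is
the package's account of the underlying models, the choices that were
genuinely open, and what the synthetic test surface does and does not
demonstrate.

## The reserve residual

Cognitive reserve is operationalised as *better-than-expected cognition
given demographics and brain structure*. Concretely, a global-cognition
composite is regressed by ordinary least squares on age, sex,
grey-matter volume, hippocampal volume and mean cortical thickness, and
the per-subject residual is the reserve measure: positive residuals mean
performance above the structural prediction.

The composite averages five within-sample z-scored subtests (verbal
fluency, processing speed, executive function, immediate and delayed
memory). Averaging rather than summing keeps the composite on an
SD-like scale — a subject one sample-SD above the mean on every subtest
scores +1 — and `combine = "sum"` is available because the combining
rule is a convention, not a substantive choice: the two differ by a
constant factor and yield identical residual *rankings*. Standardisation
is always within-dataset; when two cohorts are compared the residual is
constructed separately in each, and proxy scores from different test
versions are put on a common `[0, 1]` scale by min–max normalisation
before comparison.

Missing data are handled by complete-case deletion per fit, with the
dropped-row count carried in the fitted object. Sex may be coded with
any two-level scheme; the residuals are invariant to the coding (tested
directly), only the coefficient's sign and interpretation change.

## Connectivity matrices and motion control

An edge is the Fisher-z-transformed Pearson correlation between two
nodes' time courses. Correlations are clipped to |r| ≤ 1 − 10⁻⁷ before
`artanh` so degenerate node pairs (duplicated series) give a large
finite z rather than infinity; network strengths are sums over edges and
must stay finite. The clip margin only matters above |r| ≈ 0.9999999,
far beyond any physiological correlation.

Framewise displacement (FWD) is computed by the Power convention: the
sum of absolute frame-to-frame differences of the six rigid-body
parameters, with rotations converted to arc length on a 50 mm sphere
(configurable radius). A subject is excluded when mean FWD exceeds
0.4 mm or when any frame-to-frame movement exceeds the 97.5th percentile
of movements pooled across the whole sample. The percentile rule is a
*sample* statistic: it needs at least two subjects and its threshold
moves with the cohort, which is why exclusion is a cohort-level
operation here rather than a per-subject predicate.

Node removal (e.g. dropping 63 cerebellum/brainstem nodes from a
268-node parcellation to leave 205) is an exact submatrix operation that
preserves node order; the unique-edge count falls from 35,778 to 20,910,
i.e. the retained matrix keeps about 58% of the original edges.

## The CPM core

Edge selection correlates each of the k(k−1)/2 unique edges with the
target across training subjects and keeps the two tails separately:
positive (r > 0, p < threshold) and negative (r < 0, p < threshold).
P-values are two-sided from the t distribution on n − 2 degrees of
freedom (n − 2 − c with c covariates). With covariates, both edge and
target are residualised on the covariate design (via QR) and the
residuals are correlated — the standard partial-correlation
construction. Internally the mass-univariate pass is a centred
cross-product (BLAS), verified in the tests against `stats::cor` and
`cor.test` to 10 significant figures; a leave-one-out loop over 20,910
edges is otherwise impractical.

Network strength sums the subject's connectivity over one tail's mask —
equivalently, half the full symmetric masked-matrix sum. The combined
strength is positive minus negative strength, and each tail (positive,
negative, combined) gets its own one-predictor least-squares line from
strength to target; the combined tail is deliberately a single-predictor
model on the difference, not a two-predictor model on the pair.

Cross-validation wraps the whole procedure — selection and fitting see
only the training fold; the held-out subjects' strengths are computed
under the fold's masks and pushed through the fold's lines. Leave-one-out
is the default; repeated k-fold uses seeded partitions with fold
sizes differing by at most one, sub-seeded per repeat from the root
seed. With k = n every partition degenerates to singleton folds, and the
implementation reproduces leave-one-out bitwise (tested as an identity,
not a tolerance).

Two degenerate situations are handled explicitly rather than silently:

* **Empty masks.** If a fold selects no edge for a tail (strict
  threshold, weak signal), the strengths are constant, the slope is
  undefined, and the fold predicts its training-target mean, with the
  event counted and warned about. This is the conservative fallback —
  the model declines to use connectivity it did not select.
* **Constant inputs to evaluation.** Pearson r and R² are reported as
  undefined with a reason; MAE is always defined and still returned.

Accuracy is reported as Pearson r between predicted and observed, R²
from the regression of observed on predicted, and mean absolute error in
target units. For a one-predictor regression with intercept the R²
equals the squared correlation exactly, so the two published definitions
coincide here; this is asserted in the tests rather than assumed.

### Threshold optimisation

Edge-selection p-value thresholds are arbitrary, so a data-driven
optimiser runs the chosen cross-validation scheme over a grid (default
10⁻⁴ to 0.05, including 9 × 10⁻⁴) and picks the threshold maximising the
combined-tail out-of-fold r, breaking ties toward the stricter
threshold. When even the best r is not significantly positive the trace
is flagged non-significant — on pure-noise inputs the optimiser must not
manufacture a model.

### Aggregation and external application

For application to an external dataset, per-fold models are reduced to
one: masks are combined by a recorded rule — intersection (edges
selected in every fold; the consensus default), union, or a selection
frequency cutoff — and the per-tail intercepts and slopes are averaged
across folds. The aggregated model's provenance (rule, threshold,
covariates, fold count, edge ordering, node roster) is serialised with
it; external matrices must present the identical node roster.

A negative out-of-sample correlation is reported but flagged *not
meaningful as prediction*: predictions pointing the wrong way explain no
variance in the intended sense, and the flag makes that explicit instead
of letting a significant-looking |r| pass as success.

## Validity testing

A candidate reserve measure is tested on three criteria. *Face
validity*: positive Pearson correlation with a verbal-intelligence proxy
score. *Independence effect*: in a three-step hierarchical regression —
cognition on age, sex and cortical thickness (step 1), adding the
measure (step 2), adding the thickness-by-measure interaction (step 3) —
the step-1→2 R² increment, with a nested-model F test. *Moderation
effect*: the step-2→3 increment. The interaction is built from
mean-centred components by default so the moderation increment does not
depend on where either variable's zero sits; the raw product is
available for sensitivity analysis. No multiple-testing correction is
applied across the three criteria; the per-test α (default 0.05) is a
parameter.

Group comparisons from published descriptive statistics use the pooled
two-sample t computed from (n, mean, sd) triples with n₁ + n₂ − 2
degrees of freedom — the pooled form, not Welch, reproduces the printed
comparisons from their own summaries, and a Welch variant sits behind a
flag — and the 2×2 chi-square without continuity correction, which
likewise matches the printed sex comparison.

## The synthetic cohort generator

Because the motivating datasets are available only on request, every
downstream stage is exercised against a generator with known ground
truth. Its generative model:

* latent reserve R ~ N(0, σ_R), default σ_R = 0.6 — the scale observed
  for reserve residuals in ageing cohorts;
* a cognition signal linear in age, sex and three structural measures
  (coefficients configurable) plus R plus N(0, σ_noise); five subtests,
  each the signal plus independent noise, affinely mapped to
  test-specific units;
* edges i.i.d. Normal per subject on the Fisher-z scale (mean 0.3,
  SD 0.25). Planted edges add (positive tail) or subtract (negative
  tail) a reserve term scaled so the population edge–reserve correlation
  is exactly γ: the coupling coefficient is
  γ/√(1−γ²) · σ_edge/σ_R, which the tests verify by direct Monte-Carlo
  correlation against the stored truth;
* a proxy score loading on reserve and education; demographics with
  age-dependent structure so the residual regression has real work to
  do;
* per-subject FWD series: a tight gamma baseline scaled to a lognormal
  subject mean (median ≈ 0.18 mm), a configurable fraction of
  high-motion subjects drawn above 0.4 mm by construction, and isolated
  large spikes in a 5% subset — giving the two exclusion rules
  realistic, distinct case loads (≈10–12% excluded at defaults, the
  order observed in ageing fMRI cohorts).

Defaults are the study conditions used throughout the tests: n = 200
subjects, 205 nodes, 10 planted edges per sign, γ = 0.4. A single root
seed governs all draws; sub-streams (motion, fold shuffling, external
cohorts) use seeds derived deterministically from it, so any stage can
be reproduced in isolation.

What the generator does *not* emulate: temporal autocorrelation and
scanner noise in time series, spatial correlation among edges,
network-structured signal, site effects, or non-linear brain–cognition
relationships. Passing tests therefore demonstrate that the pipeline
recovers planted linear signal and respects its null — they do not
certify performance on real fMRI, where edge dependence typically
inflates selection variability.

## Numerical behaviour worth knowing

**The leave-one-out permutation null is not tight around zero.**
Out-of-fold predictions share fold models, so subjects are dependent and
the null SD of the prediction–observation correlation is roughly 0.15 at
n = 200 — twice the naive 1/√n. The null is also slightly negative:
fold-mean fallbacks are anticorrelated with held-out values by
construction (each prediction is the mean of everyone else), and
overfit noise edges revert out of fold. The null-control checks
therefore average the combined-tail r over several seeded permutations,
estimating the null centre instead of betting on one draw; single-draw
nulls are reported in the trace for transparency.

**Problem sizes.** The shipped checks run leave-one-out over the full
205-node, 20,910-edge connectome at n = 200 (about half a minute per
cross-validation pass with the BLAS edge-correlation path), with the
threshold grid at seven values; unit tests use 20–40-node cohorts where
every oracle can be brute-forced.

**Determinism.** Identical configs and seeds produce byte-identical
serialised reports; the end-to-end test asserts this on the report JSON.
The pipeline caches each stage keyed by a hash of its inputs, so
deleting downstream outputs and re-running resumes without recomputing
upstream stages.

## Known limitations

* Edge selection assumes exchangeable subjects; family structure or
  site nesting would need a grouped cross-validation scheme that is not
  implemented.
* The partial-correlation degrees of freedom assume a full-rank
  covariate design; rank-deficient covariates are projected out via QR
  but the reported df does not shrink further.
* The residual reserve measure inherits all measurement error of the
  cognition composite; with noisy composites the target itself is noisy
  and out-of-fold accuracy is bounded well below 1 regardless of the
  connectome's information content.
* Aggregated external application freezes the training node roster;
  there is no re-mapping between parcellations.
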