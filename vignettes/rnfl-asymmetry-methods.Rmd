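---
title: "Inter-eye RNFL asymmetry screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-eye RNFL asymmetry screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnflasym)
```

## The screening problem

Glaucomatous damage to the retinal nerve fiber layer (RNFL) is typically
bilateral but unequal, whereas healthy anatomy is nearly mirror-symmetric
between the eyes. Peripapillary OCT reports the mean RNFL thickness (µm) of
six angular sectors — TS, T, TI, NS, N, NI, with T and N spanning 90° and
the others 45° — plus the global 360° mean G. Comparing each sector between
a patient's own two eyes yields a within-patient control: the inter-eye
difference removes most between-patient anatomical variation that makes raw
thickness thresholds noisy.

The pipeline in this package: (1) compute per-patient asymmetry features,
(2) characterize their group statistics, (3) train a small class-weighted
classification tree on them, (4) evaluate screening performance. A
calibrated synthetic cohort generator stands in for patient data throughout
the tests.

## Asymmetry metrics

All metrics start from `delta = w_r − w_l` per sector. Absolute versions
discard which eye is thicker; three normalizations remove overall eye size:
by the patient's own sector sum (`Delta`), by the cohort's mean sector sum
(`Delta_bar`), and by the patient's global thickness sum (`Delta_dbar`,
which coincides with `Delta` at G). `sqrt_abs_Delta` applies a square-root
(gamma) compression to `abs_Delta`: its values live near 0, and the concave
transform spreads them apart, moving the healthy and glaucoma distributions
farther from each other on the feature scale.

Two structural identities are worth noting because the tests rely on them:

* any group mean or SD of `Delta_bar` equals the matching `delta` statistic
  divided by the fixed sector-mean sum (`deltaBarLink()`); and
* signed metrics negate, and absolute metrics are invariant, under swapping
  the eyes.

**Why absolute values work.** Signed asymmetries are zero-centered in both
groups — damage strikes either eye first with equal probability — so group
*means* carry no signal; the groups differ in *spread*. If a signed
asymmetry is approximately `Normal(0, sigma^2)`, its absolute value is
half-normal with mean `sigma * sqrt(2/pi)` (`halfNormalMean()`): the
variance gap becomes a mean gap, which single thresholds can separate.

`Delta_bar`'s denominators pool all patients of the cohort (healthy and
glaucoma together), matching how the reference statistics were produced; an
external 2×7 matrix of means can be supplied instead for prospective use.

## Group characterization

`summarizeGroups()` reports mean, sample SD (n−1 denominator) and a
two-sided p-value per feature. The group-comparison test is not dictated by
the problem, so both a rank-sum test (default: absolute metrics are markedly
non-normal) and Welch's t are exposed. R's `wilcox.test()` cannot produce an
exact p-value under ties, so for combined n ≤ 20 the package enumerates the
permutation distribution of the rank-sum statistic itself (midranks for
ties; two-sided p = twice the smaller tail, capped at 1); beyond that it
uses the normal approximation with tie-corrected variance. Rank-based
p-values are invariant under positive rescalings, so columns that differ
only by a fixed positive factor share p-values exactly.

`boxSummary()` fixes the notched-box conventions: quartiles by linear
interpolation of order statistics (R quantile type 7), whiskers at the most
extreme points within 1.5·IQR of the box, points beyond them flagged as
outliers, and notches at median ± 1.57·IQR/√n (non-overlapping notches
indicate medians differing at roughly the 5% level). Degenerate input
(constant data) yields a zero-width box and no outliers.

## The classification tree

The classifier is a from-scratch binary CART-style tree over the seven
features, built for interpretability rather than raw accuracy — the end
product is an if–then rule list a clinician can apply by hand
(`treeRules()`).

* **Impurity.** Weighted Gini, `1 − p_h² − p_g²` on summed observation
  weights. Each observation carries its class weight (`classWeights`,
  default 1/1), normalized to sum to 1 over the training set; setting
  `glaucoma = 1.5` makes missed glaucoma costlier and shifts leaf labels and
  split choices toward sensitivity.
* **Split search.** Every feature is scanned exhaustively; candidate
  thresholds are midpoints between consecutive distinct sorted values. Ties
  in impurity decrease go to the lowest feature index, then the smallest
  threshold; `value < threshold` routes left, exact equality right. These
  tie rules are arbitrary but fixed, so identical inputs give identical
  trees.
* **Budget and growth.** Complexity is controlled solely by `maxSplits`
  (ξ), the maximum number of split nodes — not tree depth. Growth is
  best-first: among all current leaves, the split with the largest
  mass-weighted impurity decrease (leaf weight × node-relative decrease) is
  applied; growth stops at ξ splits or when no leaf improves (decrease
  ≤ 1e−12, which also rejects numerically-zero gains). Best-first growth is
  what makes a split budget meaningful: a depth-first grower would spend the
  budget on the leftmost branch. There is no pruning, no surrogate splits
  and no minimum leaf size beyond one observation.
* **Prediction.** Leaves predict the class with the larger weighted
  proportion; an exactly tied leaf predicts healthy (the screening-negative
  default). Prediction is a deterministic function of the seven features.
* **Greedy is not optimal.** Like any CART grower, the greedy search can
  miss the loss-optimal tree of the same budget: a root with the best
  immediate Gini gain can foreclose a better two-split tree. The test suite
  quantifies this against an exhaustive-enumeration oracle on tiny
  instances; the package deliberately keeps the standard greedy semantics
  rather than switching to exact search.

`cvLoss()` reports stratified k-fold (default 5) cross-validated loss: folds
are drawn per class from a seeded shuffle (stratification matters with only
47 positives), and the loss is the sum of normalized weights of
misclassified held-out observations, so it lies in [0, 1]. Whether the class
weights should also enter the *reported* loss (not just training) is
ambiguous; both are exposed via `lossWeighted`, defaulting to weighted.

## Screening evaluation

Glaucoma is the positive class everywhere. `screeningMetrics()` returns
exact ratios (accuracy, sensitivity, specificity, precision); rounding —
half away from zero to 4 decimals, `roundHalfUp()` — happens only at report
time. `reconstructConfusion()` inverts published rate tables into integer
counts via `TP = round(TPR·n_g)`, `TN = round(TNR·n_h)`; on matrices whose
rates are reported at full precision this is exact, and comparisons against
published tables use a 1e−4 tolerance because some printed values are
truncated rather than rounded (e.g. 183/207 printed as 0.8840, 149/160 as
0.9312).

## The synthetic cohort generator

No patient-level data ship with the package; `generateCohort()` draws
cohorts with the statistical structure the analysis assumes, calibrated to
the published summary statistics that `referenceSectorMeans()` and
`referenceDeltaStats()` record (group sizes 160/47; per-sector, per-group
difference means and SDs; per-eye sector mean levels; age/sex marginals).

Construction per patient: a shared bilateral level `b_S = base_S + u`,
`u ~ Normal(0, betweenPatientSd)` with `base_S` the midpoint of the
published right/left sector means; a difference vector
`delta ~ MVN(mu_group, Sigma_group)` with exchangeable correlation ρ; eyes
`w_r = b + delta/2`, `w_l = b − delta/2`; rejection-resampling of the rare
patient with a non-positive thickness (negligible at these scales, and it
keeps the moments clean relative to truncation). Splitting `delta` half to
each eye hits both the difference distribution and the per-eye levels by
construction. G is always computed as the angle-weighted sector mean, never
drawn, so the `Delta_dbar` denominators are internally consistent and the
global difference is exactly the angle-weighted combination of sector
differences.

That last identity gives ρ a closed form: with weights `a_S = extent_S/360`,
`var(delta_G) = (1 − ρ)·Σ a²σ² + ρ·(Σ aσ)²`. `calibrateCorrelation()` solves
this so the emergent global-difference SD matches its published value
(healthy 6.5895 µm, glaucoma 25.8728 µm), yielding ρ ≈ 0.073 (healthy) and
≈ 0.564 (glaucoma) under the default sector SDs — the minimal correlation
structure reproducing both the sector-wise and the global spreads.

Choices where the published summaries are silent:

* `betweenPatientSd = 10` µm for the shared level heterogeneity — a
  realistic bilateral spread for adult peripapillary RNFL; no calibration
  target depends on it.
* Differences are drawn multivariate normal. The published characterization
  argues normality for the signed metrics, so this is the natural model,
  but it is also the generator's main idealization: real absolute-asymmetry
  means sit somewhat *below* the half-normal value implied by their SDs
  (heavier center, occasional gross outliers), proportionally more so for
  G. Consequently the simulated global feature, while still the strongest
  single discriminator on average, dominates the sector features less
  decisively than in the real cohort — worth remembering when reading the
  end-to-end tree tests: they demonstrate the pipeline's behavior under the
  generator's assumptions, not the clinical performance of the method.
* Age and gender are drawn from the published marginals purely for realism;
  they are never features.

Everything is a deterministic function of `seed` — identical seeds give
byte-identical cohort CSVs.

## Data model and I/O

Cohorts are `RNFLCohort` objects (SummarizedExperiment with `right`/`left`
7×n assays, µm; diagnosis, age, gender in `colData`). The CSV interface is
long-format, one row per eye, header
`patient_id,eye,label,TS,T,TI,NS,N,NI,G`; rows lacking a partner eye, with
duplicate (patient, eye) pairs, or with mixed diagnoses within a patient are
rejected by name — mirroring a design that only admits patients with two
same-diagnosis eyes. A supplied G column is taken verbatim (device-reported
global means can differ from the angle-weighted sector mean by a fraction of
a µm, presumably from per-A-scan averaging or rounding; the package records,
it does not reconcile); an absent or empty G is computed with
`angleWeightedGlobal()`. Thicknesses are written with six decimals, so a
write–read round trip reproduces a cohort to that precision.

## Problem sizes in the tests

The test suite works at the cohort's native size (207 patients) for pipeline
checks, 2×10⁴ patients for distributional calibration checks (SD and
half-normal law within ~2%), 10⁵ draws for the Monte-Carlo half-normal
check (1%), 200 instances of n ≤ 8 for the tree-oracle comparison, and 20
seeds for the end-to-end screening band.

## Known limitations

* Sector means are the finest resolution; no per-A-scan (angle-resolved)
  asymmetry is modeled or accepted.
* The generator does not emulate OCT acquisition artifacts — speckle,
  segmentation error, vessel shadowing — nor non-normal tails of real
  asymmetry distributions (see above).
* The tree is intentionally minimal: no pruning, surrogate splits, missing
  value handling, or ensembles. Inputs must be complete.
* Cross-validated losses depend on fold randomization; they are reproducible
  given `seed` but not comparable across seeds to a third decimal.
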