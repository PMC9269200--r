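# rnflasym

Glaucoma thins the retinal nerve fiber layer (RNFL), and it usually does so
*asymmetrically* between a patient's two eyes, while healthy inter-eye
differences are small and centered at zero. `rnflasym` turns paired
peripapillary OCT sector thicknesses into inter-eye asymmetry features and
builds small, clinician-readable decision trees for glaucoma screening. It is
aimed at researchers working with per-sector RNFL thickness exports
(temporal-superior TS, temporal T, temporal-inferior TI, nasal-superior NS,
nasal N, nasal-inferior NI, plus the global mean G) for both eyes of each
patient.

## What it computes

For patient *i* and sector *S*, with right/left mean thicknesses
*w<sup>r</sup><sub>S,i</sub>* and *w<sup>l</sup><sub>S,i</sub>* (µm), the
package implements nine asymmetry metrics built on the inter-eye difference
δ<sub>S,i</sub> = w<sup>r</sup><sub>S,i</sub> − w<sup>l</sup><sub>S,i</sub>:

| metric | definition | range |
|---|---|---|
| `delta`, `abs_delta` | δ, \|δ\| | µm |
| `Delta`, `abs_Delta` | δ / (w<sup>r</sup> + w<sup>l</sup>), and its absolute value | [−1, 1], [0, 1] |
| `Delta_bar`, `abs_Delta_bar` | δ / (w̄<sup>r</sup><sub>S</sub> + w̄<sup>l</sup><sub>S</sub>), normalized by the cohort's mean sector thicknesses | [−1, 1], [0, 1] |
| `Delta_dbar`, `abs_Delta_dbar` | δ / (w<sup>r</sup><sub>G</sub> + w<sup>l</sup><sub>G</sub>), normalized by the patient's global thickness sum | [−1, 1], [0, 1] |
| `sqrt_abs_Delta` | √(\|δ\| / (w<sup>r</sup> + w<sup>l</sup>)) — square-root (gamma) compression | [0, 1] |

Signed metrics are zero-centered in both groups; what separates glaucoma is
their *variance*. Taking absolute values turns a zero-mean normal into a
half-normal with mean σ·√(2/π), converting the variance gap into a mean gap
that a threshold — and hence a decision tree — can exploit
(`halfNormalMean()`).

On top of the features the package provides:

- group characterization (`summarizeGroups()`): mean ± SD per sector and
  diagnosis group with rank-sum (or Welch) p-values, plus notched box-plot
  quantities (`boxSummary()`);
- a from-scratch CART-style classifier (`growTree()`): weighted Gini
  impurity, exhaustive midpoint threshold scan, best-first growth under a
  maximum-number-of-splits budget ξ, per-class observation weights, and
  stratified 5-fold cross-validated misclassification loss (`cvLoss()`);
- screening evaluation (`confusionCounts()`, `screeningMetrics()`):
  accuracy, sensitivity, specificity and precision with glaucoma as the
  positive class, and `reconstructConfusion()` to recover integer confusion
  matrices from published rate tables;
- a calibrated synthetic cohort generator (`generateCohort()`): paired-eye
  records whose group sizes (160 healthy / 47 glaucoma), per-sector
  difference distributions and global-difference SDs match the published
  clinical cohort the defaults are calibrated to.

## Worked example

```r
library(rnflasym)

cohort <- generateCohort(seed = 42)
cohort
#> RNFLCohort: 207 patients (160 healthy, 47 glaucoma)
#>   sectors: TS T TI NS N NI; G angle-weighted

af <- asymmetryFeatures(cohort, "sqrt_abs_Delta")
summarizeGroups(af)
#>  feature mean_h    sd_h n_h mean_g   sd_g n_g   p_value
#>       TS 0.2134 0.08914 160 0.3313 0.1421  47 1.409e-07
#>        T 0.2171 0.10090 160 0.3036 0.1372  47 3.879e-05
#>       TI 0.1901 0.08672 160 0.3414 0.1305  47 1.738e-11
#>       NS 0.2534 0.10010 160 0.3151 0.1409  47 3.523e-03
#>        N 0.2449 0.09553 160 0.3100 0.1250  47 1.426e-03
#>       NI 0.2272 0.10760 160 0.3083 0.1455  47 1.035e-03
#>        G 0.1551 0.06216 160 0.2763 0.1115  47 3.367e-11
```

Every sector separates the groups (all rank-sum p < 0.01), the global
feature G most strongly — the compressed absolute asymmetry of the whole
contour is the single best discriminator. A three-split tree with the
glaucoma class up-weighted 1.5× stays readable:

```r
tree <- growTree(af, maxSplits = 3, classWeights = c(healthy = 1, glaucoma = 1.5))
tree
#> AsymmetryTree: 3 split(s) (budget 3), weights h=1 g=1.5, metric 'sqrt_abs_Delta'
#> if G < 0.292691 then
#>   if TI < 0.273833 then
#>     if TS < 0.405379 then
#>       predict healthy (healthy 0.949, glaucoma 0.051, n=144)
#>     else (TS >= 0.405379)
#>       predict glaucoma (healthy 0.000, glaucoma 1.000, n=2)
#>   else (TI >= 0.273833)
#>     predict glaucoma (healthy 0.442, glaucoma 0.558, n=35)
#> else (G >= 0.292691)
#>   predict glaucoma (healthy 0.053, glaucoma 0.947, n=26)

cvLoss(af, maxSplits = 3, classWeights = c(healthy = 1, glaucoma = 1.5), seed = 42)
#> [1] 0.1410372

cm <- confusionCounts(diagnosis(cohort), predict(tree, af))
cm
#>  TP  FP  TN  FN
#>  42  21 139   5
roundHalfUp(screeningMetrics(cm), 4)
#>    accuracy sensitivity specificity   precision
#>      0.8744      0.8936      0.8688      0.6667
```

Here the tree screens the synthetic cohort with 87% accuracy and 89%
sensitivity in-sample; the cross-validated weighted loss is 0.141. Patients
whose global asymmetry exceeds the root threshold are flagged directly;
below it, temporal-sector asymmetry picks up focal damage.

A thin command-line wrapper (`inst/cli/rnflasym`) exposes the same pipeline
as `simulate | characterize | train | evaluate | rules` subcommands, and
cohorts move through a plain CSV interface (`readCohortCsv()`,
`writeCohortCsv()`; header `patient_id,eye,label,TS,T,TI,NS,N,NI,G`).

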