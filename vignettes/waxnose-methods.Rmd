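---
title: "Grading paraffin-wax odor from total ion spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading paraffin-wax odor from total ion spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waxnose)
```

## The problem

Food-grade paraffin wax must be practically odorless: residual aromatics
(toluene and other alkylbenzenes) left by an incomplete hydrogenation give it
a smell that disqualifies it from food contact. The reference assessment is a
five-expert sensory panel grading odor on the ASTM D1833 five-point scale
(*None* to *Very Strong*) — slow, subjective, and hard to compare across
laboratories.

`waxnose` implements an instrumental alternative: a headspace GC/MS run is
collapsed into a **total ion spectrum** (TIS) — the sum of each m/z channel's
intensity over the whole chromatographic program — so the instrument behaves
like an MS-based electronic nose in which every fragment ion is one sensor.
The TIS is time-independent, which sidesteps retention-time alignment
entirely, and after **base-peak normalization** (every channel divided by the
sample's own maximum) it is a unit-free fingerprint of the wax's aroma.
Fingerprints over m/z 50–550 (501 nominal-mass channels) are stacked into a
channels × samples matrix `D` that feeds every downstream model. Odor grades
are emulated by blending non-hydrogenated into food-grade wax at 0/25/50/75/
100%, mapping onto the five ASTM grades.

## Headspace optimization (Box–Behnken + RSM)

Three factors govern how much volatile material reaches the vapor phase:
incubation temperature (100–140 °C), agitation (250–750 rpm) and sample
quantity (0.2–0.6 g). `bbd_design()` builds the 3-factor Box–Behnken design:
12 edge runs (each factor pair at (±1, ±1) with the third at its center) plus
6 replicated center points, in coded units where low/mid/high map affinely
onto −1/0/+1.

The response is the Euclidean distance between the normalized TIS of a
*Slight* (25%) and a *Very Strong* (100%) sample — larger distance means the
conditions discriminate odor grades better. `fit_quadratic()` fits the full
second-order polynomial

$$Y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
      \sum_{i<j} \beta_{ij} x_i x_j + \epsilon$$

by ordinary least squares in coded units. Inference follows classical DOE
practice:

* **Pure error** is estimated from the six center replicates (5 df), and
  every term F statistic divides the term mean square (type-III,
  $b_j^2 / C_{jj}$; $8 b_j^2$ for a linear term of this design) by the
  pure-error mean square. This denominator choice is deliberate — it is what
  classical DOE software reports, and a residual-MS denominator gives
  materially different p-values.
* **Lack of fit** partitions the residual SS into pure error and lack of fit
  (3 df here); a large p-value says the quadratic form is adequate.
* `standardized_effects()` reports $t = b_j / \mathrm{se}(b_j)$ per term
  (Pareto-chart data); $t^2$ equals the ANOVA F for these single-df terms.
* `optimize_surface()` maximizes the fitted polynomial over the coded cube by
  multi-start L-BFGS-B, cross-checked against a coarse-to-fine grid scan with
  a 0.001 final step. The search is constrained to the cube; on the bundled
  reference experiment the maximizer is the corner (+1, −1, +1), i.e. 140 °C,
  250 rpm and the top of the sample-quantity range. When mapping coded
  optima to natural units the package always applies the affine factor map.

```{r doe}
fit <- fit_quadratic(example_bbd_study())
round(fit$coefficients, 5)
c(r_squared_pct = 100 * fit$r_squared, lof_p = lack_of_fit(fit)$p)
optimize_surface(fit)$coded
```

Incubation time is handled separately: `kinetic_anova()` runs a classical
one-way ANOVA of replicate distances across incubation times (5–25 min). A
non-significant result at the 95% level means the headspace has equilibrated,
so the shortest time is adopted; the degenerate all-equal case is reported as
F = 0, p = 1 (nothing to reject). Method precision uses `precision_cv()`,
the coefficient of variation of replicate distances with a 10% acceptance
limit.

## Exploratory analysis

`agglomerative_coefficient()` scores candidate linkages (average, single,
complete, Ward) by the agnes-style coefficient
$\mathrm{AC} = \mathrm{mean}_i\,(1 - h_{\mathrm{first}}(i)/h_{\mathrm{final}})$;
values near 1 indicate strong structure. "Ward" is implemented in the
Ward.D2 (squared-distance update) convention, stated explicitly because the
name is ambiguous across ecosystems. `run_hca()` returns the merge tree and
exports dendrograms as Newick plus a merge CSV so any plotting layer can
render them.

`run_pca()` mean-centers but does **not** unit-variance scale by default:
the columns already share the 0–1 base-peak scale, and leaving variances
intact keeps loadings concentrated on the dominant ions (a `scale.` flag is
exposed). Since the preprocessing convention of the original analysis is not
recorded, exact variance splits are convention-dependent; this default is the
package's own choice. Component signs are fixed (largest-|loading| element
positive) so results are deterministic.

## Supervised models

`split_data()` makes a stratified 70/30 split (ceiling per class), which on
75 samples yields the 55/20 partition with all five grades on both sides.
All tuning uses stratified, seed-fixed 5-fold CV with exported fold indices
so any grid search can be replayed externally.

* **Gaussian SVM / SVR** (`tune_svm()`, `train_svm()`, `train_svr()`): the
  kernel is $k(x, x') = \exp(-\sigma\|x-x'\|^2)$, so the σ here coincides
  with the γ reported by libsvm-style tools. The grid is exponential,
  $\log_2 C$ and $\log_2 \sigma$ from −10 to 10 in 0.5 steps (41 × 41 = 1681
  combinations); classification picks the best CV accuracy with ties broken
  by smallest C then smallest σ, regression the lowest CV RMSE. SVR keeps
  ε = 0.1 fixed. Spectra are not re-scaled inside the SVM (they are already
  base-peak normalized).
* **Random forest** (`rf_fit()`): mtry defaults to √p (classification) and
  p/3 (regression) — 22.38 → 22 and 167 for 501 channels — with an optional
  cross-validated sweep of the tree count (2–100 by 2) and a final forest of
  100 trees. Importances are permutation-based (OOB accuracy decrease),
  rescaled to 0–100%. `importance_reduce()` keeps channels above a 70%
  relative-importance threshold (falling back to the top-k with a warning if
  none clears it), `channel_anova()` confirms grade dependence per selected
  channel, and a reduced refit via `subset_channels()` provably uses only
  the selected set. For a reduced set of p channels the default mtry is
  floor(√p).
* **PLSR** (`pls_fit()`): NIPALS PLS1 on mean-centered data, written
  in-package and cross-checked in the test suite against an independent PLS
  implementation. The component count minimizes 5-fold CV RMSE; variable
  importances are weighted sums of absolute regression coefficients across
  component counts, weighted by the response variance each component
  explains, scaled to a 100% maximum.
* **Metrics**: accuracy and unweighted Cohen's kappa for classification;
  RMSE and R² for regression. R² is reported in the squared-Pearson
  convention of common tuning frameworks *and* as 1 − SS\_res/SS\_tot, since
  the two differ under calibration offsets.

## The synthetic-data generator

No public instrument data exist for this problem, so `make_study()` simulates
the full design: 5 lots × 5 blend levels × 3 replicates = 75 runs labelled
`"25%_A_R1"`-style. Each marker ion is emitted as a single Gaussian-in-time
chromatographic peak whose *area* equals its expected normalized intensity —
peak shape is deliberately cosmetic, because the TIS integrates time out.
Three stochastic layers sit on top:

* a per-(lot, ion) multiplicative log-normal lot effect (`lot_sd`, default
  0.05), identical for all runs of a lot — simple, positive, and the source
  of the sub-grade structure visible in dendrograms;
* additive Gaussian intensity noise scaled so the collapsed TIS channel noise
  has s.d. `noise_sd` (default 0.02) on the normalized scale, truncated at
  zero for physical non-negativity;
* everything is driven by explicit integer seeds: identical seeds give
  bit-identical runs.

The grade structure lives in `default_marker_table()`: grades *None*/*Slight*
peak at m/z 97 and the higher grades at m/z 92; m/z 92/118/157 are ≥ 0.75
for *Slight* but < 0.5 for *None*; seven ions (79, 95, 97, 118, 157, 188,
221) fade monotonically from *Moderate* to *Very Strong*; and m/z 91
(tropylium, the alkylbenzene signature) rises steeply with blend percentage,
which is why it dominates PC1 and the PLSR importances. Published sources
state these orderings only qualitatively, so the numeric bar heights are the
package's own calibration chosen once to satisfy the inequalities; the table
is plain data and fully editable. With noise and lot effects switched off the
normalized TIS reproduces the table exactly, which the tests exploit.

What the generator does **not** emulate: headspace physics (temperature and
agitation kinetics), co-eluting interferents, detector saturation, drifting
baselines, or real lot chemistry. Passing tests therefore demonstrate that
the analysis machinery recovers structure that is genuinely present at
realistic noise levels — not that real waxes are this clean. For the DOE
stack the stand-in is `surrogate_surface()`, a known quadratic polynomial
(defaulting to the reference experiment's fitted coefficients) that makes
coefficient recovery exactly testable.

## Numerical choices and degenerate inputs

* Profile-mode m/z values are binned to nominal mass by rounding
  (ties-to-even, R's default); the TIS window defaults to 50–550 even though
  acquisition typically scans to 600 — both bounds are arguments.
* All-zero spectra cannot be normalized and raise an error naming the
  sample; distances are only defined on normalized spectra.
* A constant ANOVA response yields zero term SS; identical kinetic groups
  report F = 0, p = 1; designs without replicated centers refuse pure-error
  based inference rather than silently switching denominators.
* Surface optimization accepts the flat-surface case (any point reported);
  grid refinement guards against local-optimum misses, and ties in the SVM
  grid are broken deterministically.
* The pipeline (`run_pipeline()`) derives every stage seed from one master
  seed and logs file hashes, so a rerun under the same configuration is
  byte-identical.

## Problem sizes used in the tests

The bundled test and demonstration workloads use the 75-run study at 120
scans per run, tuning grids reduced to a handful of exponents, and 5-seed
averages for the stochastic recovery checks; the kinetic null calibration
uses 1000 simulated experiments. These sizes were chosen as the smallest at
which the statistical properties under test are stable.

## Known limitations

* The generator's five grade signatures are discrete; it cannot produce
  intermediate blends, so regression error estimates are optimistic relative
  to a continuous adulteration process.
* The agglomerative coefficient grows with sample count for fixed structure;
  compare linkages, not studies, with it.
* PLS1 only (single response); no multi-response PLS2.
* mzML support targets centroided unit-mass spectra; vendor formats are out
  of scope.
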