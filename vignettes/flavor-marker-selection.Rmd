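---
title: "Linking sensory panels to metabolomics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking sensory panels to metabolomics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavorlink)
```

# The problem

A sensomics study rates a set of food products — here, tomato soups whose
recipe varies over five compositional factors (oil type, tomato dosage,
yeast-derived flavor product, yeast dosage, heating duration) — with a
trained quantitative descriptive analysis (QDA) panel, and profiles the same
products with untargeted LC-MS (non-volatiles) and GC-MS (volatiles).
The analysis asks three questions:

1. Which sensory attributes let the panel discriminate the products
   (product-effect F statistics)?
2. How well can each platform's chemical features predict each attribute's
   per-product sensory response (cross-validated Q²), and classify each
   compositional factor (balanced accuracy)?
3. Which individual features carry that prediction (marker ranking and
   minimal predictor sets), and do markers replicate across platforms
   (cross-platform correlation)?

`flavorlink` implements this pipeline end to end, together with a synthetic
study generator that carries known ground truth so that every stage can be
validated by recovery experiments.

# Panel-score standardization

Assessors differ in where they anchor the scale (offset) and how much of it
they use (scale). With `I` assessors, `J` products and `K` attributes, the
raw score `y[i, j, k]` is standardized one attribute at a time:

    z[i, j, k] = (y[i, j, k] - mean_ik) / sd_ik

where `mean_ik` and `sd_ik` are the assessor's mean and sample SD across
products. Each retained (assessor, attribute) slice then has mean 0 and
SD 1 by construction. For interpretability the scores are mapped back to
score units:

    ystar[i, j, k] = mean_k + z[i, j, k] * sp_k

with `mean_k` the attribute's overall mean and `sp_k` a pooled SD across
assessors. The per-product **sensory response** `nu[j, k]` is the mean of
`ystar` across assessors; it is the regression target for the marker
models.

**Pooled-SD modes.** Some QDA write-ups print the pooled SD as
`sum_i sd_ik / (I * (J - 1))`. That expression is an arithmetic mean SD
shrunk by `1/(J - 1)`: it is not in SD units and compresses the
back-transformed spread by roughly an order of magnitude at `J = 27`.
Because the stated purpose of the back-transform is to *restore* the
original means and spreads, the package defaults to the conventional
root-mean-variance form `sp_k = sqrt(sum_i sd_ik^2 / I)`, which does
restore the spread exactly when every slice is standardized to SD 1. The
printed form remains available as `pooled_sd(..., mode = "literal")`, and
the two are distinguished by tests. Since both back-transforms are affine
per attribute, the choice does not change product rankings, F statistics on
standardized data, or any correlation-based downstream result — only the
units of `ystar`.

**Degenerate slices.** An assessor who gives an attribute the same score
for every product carries no product information and has `sd_ik = 0`; the
slice is dropped with a warning (configurable to a hard error). Sessions
are averaged per (assessor, product, attribute) before modeling, because
the standardization model indexes scores by assessor, product and
attribute only.

# Product-effect F statistics

Per attribute, the package fits a linear mixed model with product as a
fixed effect and assessor as a random intercept (REML), and reports the
product-effect F with Satterthwaite denominator degrees of freedom, plus
the critical F at the chosen alpha (default 0.05). For a complete balanced
panel this F coincides with the classical two-way (product + assessor
blocks) ANOVA F — the test suite checks agreement to six decimals — while
the mixed model also handles incomplete allocations. Whether raw or
standardized scores are supplied is the caller's choice; both are valid
inputs and standardization leaves the balanced-case F invariant to
per-assessor affine transformations.

# Feature-table preprocessing

The pipeline starts from post-peak-picking feature tables (samples x
features intensities with sample metadata) and applies, in a fixed order:

1. **Blank filter** (default ratio 5): drop features whose mean study
   intensity is below 5 times the mean blank intensity. A feature absent
   from blanks is never dropped.
2. **QC-RSD filter** (default 0.30): drop features whose relative SD over
   pooled-QC injections exceeds 30%. Both thresholds are conventional
   untargeted-metabolomics choices; they are exposed as parameters.
3. **Log transform** (natural log): zeros replaced per feature by half its
   minimum positive value before logging. The base is immaterial after
   autoscaling; natural log is used throughout.
4. **Technical-replicate averaging** on the log scale, one row per product.
5. **Autoscaling** (centering, unit sample SD per feature), so PLS sees
   comparable leverage across features.

Filters precede the transform because their statistics (fold changes, RSD)
are defined on raw intensities. Every step appends its parameters and
removed feature ids to a processing log; replaying the log on the raw table
reproduces the processed table bit-for-bit, which the tests exercise.
`feature_pca()` provides the exploratory view (SVD, sign fixed so each
component's largest-magnitude loading is positive).

# PLS, VIP and the metrics

PLS is implemented as NIPALS with standard deflation; the single-response
case uses the closed per-component weights, and the one-component solution
is checked against a closed-form oracle while multi-component predictions
are checked against an independent reference implementation (mixOmics) to
1e-8. PLS-DA trains on one-hot dummy responses and decodes by argmax with
ties going to the first training label.

Feature importance is VIP,
`VIP_f = sqrt(p * sum_a SS_a (w_af/||w_a||)^2 / sum_a SS_a)`, with `SS_a`
the Y-variance captured by component `a`; squared VIPs average to 1, so
VIP > 1 marks above-average importance. Random-forest regression ranks by
unscaled permutation importance (out-of-bag MSE increase), delegated to the
randomForest package.

Performance metrics follow their defining formulas: balanced accuracy
`BACC = sum_i (TPR_i + TNR_i) / (2L)` (0.5 is the binary chance level),
`Q² = 1 - PRESS/TSS` on out-of-fold predictions, and RMSEP.

# The rdCV selection engine

`rdcv_select()` wraps the estimators in repeated double cross-validation
with iterative feature elimination:

- **Outer loop:** stratified folds (by class, or by response quantile for
  regression); default 4 folds for classification, 9 for regression.
- **Inner loop:** on each outer-training set, `n_outer - 1` stratified
  folds walk a descending feature ladder (10% of retained features dropped
  per rung, at least one, floor 2). At each rung the engine is fitted per
  inner fold; the PLS component count is chosen as the argmin of inner
  error over 1..5; features are ranked by mean VIP (or permutation MDA)
  and the lowest-ranked are eliminated.
- **Set sizes:** inner classification fitness is the misclassification
  count, regression fitness the squared prediction error. The minimal
  rung size whose error is within 5% of the curve minimum is `n_min`, the
  largest such size `n_max`, and the rung nearest their geometric mean
  `n_mid`.
- **Outer estimate:** the engine is refitted on the full outer-training
  set at each chosen size and predicts the held-out fold; performance
  (BACC or Q²) is computed from the pooled out-of-fold predictions only,
  never from training fits, so label permutation drives it to chance — a
  leakage sentinel test enforces this.
- **Rank fusion:** per rung, present features take their importance rank
  and absent features take rung size + 1; ranks are averaged over rungs,
  outer folds and repetitions. Set sizes are fused by medians (ordered to
  keep `n_min <= n_mid <= n_max`), and the sets are the top-ranked
  features at those sizes, hence nested by construction.

Fold reshuffling across repetitions, the geometric ladder, and
arithmetic-mean rank fusion are the package's own concrete choices within
the rdCV family; they are fixed, documented here, and deterministic under
the master seed (per-repetition child seeds are derived from it). The
reported `performance` is the mid-set value, with all three exposed in
`performance_by_set`; pooling outer predictions (rather than averaging
per-repetition values) is the default because it uses every prediction
exactly once per repetition. Within the rdCV engine, RF fits default to 100
trees per fit (the standalone `rf_rank()` default is 500) — a deliberate
trade of per-fit variance against the number of repeated fits the ladder
requires; repetition averaging recovers the stability.

Defaults of 500 (classification) and 200 (regression) repetitions match
standard practice for final analyses; the examples and tests in this
package run 6-30 repetitions, which is sufficient for the calibration and
recovery properties they assert.

# The synthetic study generator

`simulate_study()` generates a coupled bundle emulating the study design:
27 products over the five factors, a 14-assessor panel scoring 26
attributes in 4 sessions on a 0-100 scale, and two platforms with QC,
blank and technical-replicate structure (QCs every 10 injections; 12
products injected in quadruplicate).

- **Panel model:** `y = clip(a_i + b_i * mu[j, k] + eps, 0, 100)` with
  per-assessor offsets `a_i ~ N(0, 6^2)` score units, gains
  `log b_i ~ N(0, 0.12^2)`, and session-level noise
  `eps ~ N(0, 6^2)`. The true response `mu` comes from an effect map tying
  attributes to design factors with graded magnitudes (e.g., garlic flavor
  +22 for the G28 yeast arm, down to a null attribute). The panel noise
  magnitudes are free parameters chosen as realistic for a trained panel
  on a 0-100 scale — they are not estimates from any particular study.
  Clipping at the scale bounds is tracked; defaults keep the clipped
  fraction well below 1%.
- **Feature model:** marker features follow
  `log x = baseline_f ± marker_effect * c_j + technical noise`, where
  `c_j` is the attribute's true response standardized across products;
  non-markers are baseline + noise; background features are as abundant
  in blanks as in study samples (blank-filter targets); QCs are the pooled
  study mean plus technical noise; optional correlated blocks share a
  per-product latent factor as an adduct/isotope analogue. Technical
  noise is log-normal with SD `sqrt(log(1 + cv^2))`, default CV 5%.
- **Incomplete allocation:** coverage below 1 uses a cyclic scheme with
  evenly staggered, per-session-rotated windows so every product appears
  in every session.

What the generator deliberately does **not** emulate: chromatographic peak
shape, retention time, m/z, batch drift, intensity-dependent
heteroscedasticity, or inter-assessor disagreement beyond affine bias.
Passing recovery tests therefore demonstrates the statistical machinery is
correct under the stated model, not that real soups behave this simply.

# Numerical and scale choices

Problem sizes in the test suite are chosen to finish in minutes on one
core: null calibration uses 30 samples x 100 features with 30 repetitions
over 5 master seeds; marker recovery uses 27 products x 500 features with
25 repetitions; pipeline coherence uses 8 graded attributes at ~100
features per platform with 6 repetitions. Degenerate inputs (constant
slices, all-zero features, rank-deficient PCA, two-feature ladders, exact
PLS-DA ties) all have defined, tested behavior. CSV serialization uses 17
significant digits so write/read round trips are bit-exact.

# Known limitations

- The mixed-model F uses a random assessor intercept only; no
  assessor-by-product interaction or multiplicative assessor models (MAM)
  are fitted.
- No batch-drift or injection-order correction is applied; the QC
  machinery monitors but does not correct.
- Isotope/adduct deduplication is assumed done upstream; correlated
  feature blocks are retained and will share credit in rankings.
- Q² from pooled outer predictions can differ slightly from
  per-repetition averaging in small samples; only pooling is exposed as
  the headline number.
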