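---
title: "Methods: an OPLS disease severity index for preclinical dementia"
author: "dsindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an OPLS disease severity index for preclinical dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsindex)
```

## The problem and the model

Structural MRI morphometry in Alzheimer's disease (AD) shows a
characteristic multivariate pattern — medial temporal and parietal atrophy
with ventricular enlargement — rather than change in any single region.
`dsindex` condenses that pattern into a single per-subject score. A binary
OPLS discriminant model is trained on AD patients versus healthy controls
(HC); subjects from a third group (here: subjective memory decline, SMD)
are then projected onto the model *as unseen data*, and their predicted
response is read as a **disease severity index**: ~0 means a control-like
brain, ~1 an AD-like brain. An index at or above 0.5 calls the subject
AD-like.

OPLS splits the systematic variation of the predictor matrix into a
*predictive* part (correlated with the class code) and *orthogonal* parts
(structured variation unrelated to class, e.g. within-group anatomy).
With `X` the preprocessed subjects-by-features matrix and `y` the centred
0/1 class code, each of the `nOrth` orthogonal components is computed as

```
w* = Xᵀy / ‖Xᵀy‖          t* = X w*         p* = Xᵀt* / (t*ᵀt*)
w_o ∝ p* − (w*ᵀp*) w*      t_o = X w_o       p_o = Xᵀt_o / (t_oᵀt_o)
X ← X − t_o p_oᵀ
```

and the final predictive component on the deflated matrix is
`w ∝ Xᵀy`, `t = X w`, `c = yᵀt/(tᵀt)`. The index of a new subject is
`c·t(x) + ȳ` after sequentially removing the stored orthogonal
components from `x`. Two exact identities follow from the construction
(both are asserted in the test suite): orthogonal scores have zero sample
covariance with `y`, and adding any linear combination of stored
orthogonal loadings to a subject leaves its index unchanged. With
`nOrth = 0` the model reduces to single-component PLS1 with the
closed-form weight `w ∝ Xᵀy`.

We deliberately fit a single predictive component: with a binary response
there is only one class-separating direction, and extra predictive
components would have to be justified out-of-sample.

## Preprocessing and leakage control

Volume measures scale with head size, so total intracranial volume (ICV)
is treated as a nuisance covariate. Two mechanisms are provided, because
"include ICV as a covariate" genuinely admits both readings:

* **residualize** (default): every volume-kind column is replaced by the
  residual of a straight-line fit of the column on ICV; thickness columns
  are untouched. After this step each adjusted volume column is exactly
  uncorrelated with ICV on the training rows.
* **append**: ICV enters as one extra standardizable feature column.

Columns are then mean-centred and scaled to unit variance (sd with the
n−1 denominator; Pareto scaling, dividing by √sd, is available as an
option). Zero-variance columns are dropped with a warning and recorded.

Every statistic in this chain is estimated **only on training rows** and
stored with the model; projected subjects are transformed with the stored
parameters. During cross-validation the whole chain (ICV fit included) is
re-estimated inside each training split. The test suite checks this by
perturbing held-out rows and asserting the fitted parameters do not move.

## Cross-validation and model size

Model quality is `Q²(Y) = 1 − PRESS/SS`, computed from a stratified,
seeded 7-fold split in which every subject is predicted exactly once by
the fold that held it out; `SS` is taken about the overall response mean.
By the field's convention Q² > 0.05 counts as statistically meaningful and
Q² > 0.5 as a good model; on label-permuted or pure-noise data the
cross-validated Q² of this implementation is at or below zero on average
(property-tested). Sensitivity and specificity are computed from the
cross-validated predictions thresholded at 0.5 with the disease class
positive.

The number of orthogonal components is not knowable a priori, so
`selectOrthogonalComponents()` grows the model greedily: it returns the
smallest `n` for which the cross-validated gain `Q²(n+1) − Q²(n)` falls
below 0.01 (capped at 5). On data with a planted class-unrelated
structured component this selects at least one orthogonal component; on
noise it selects zero.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable end to
end; its defaults are fixed at the study conditions of the cohort the
method was developed for and are not tuning knobs:

* group sizes HC 69, SMD 86, MCI 45, AD 38; 11 of the 86 SMD subjects are
  drawn from the AD feature distribution (the hidden truth is stored in
  colData `truth_adlike` and excluded from modelling);
* the planted contrast puts d = −2.5 (standardized units) on hippocampus,
  entorhinal, inferior parietal, amygdala and precuneus measures and
  d = +2.5 on the inferior lateral ventricles; MCI receives half the
  contrast. The magnitude 2.5 is a calibration choice — large enough that
  a correctly implemented model reaches Q² well above the 0.5 "good
  model" bar and near-perfect CV classification, mirroring the strong
  separability reported for real AD-vs-HC morphometry — not an empirical
  effect-size estimate;
* features are multivariate normal with a single-parameter exchangeable
  correlation (default 0.3) inside each block (cortical thickness,
  cortical volume, subcortical volume). One parameter keeps the generator
  analysable; real covariance is far richer;
* ICV ~ N(1.5×10⁶, 1.5×10⁵) mm³; volume features are multiplied by
  (ICV/mean)^coupling with coupling 1 (proportional scaling);
* follow-up visits at months 0, 18, 36, 54, 72, 90. Each subject draws
  one terminal outcome from its group's frequency table, calibrated to
  the published follow-up counts — e.g. for the planted AD-like SMD
  subpopulation 6/11 convert to AD and 2/11 die, so 8/11 progress in
  expectation. Death replaces (not follows) conversion, matching the
  mutually exclusive outcome rows of the source table. A small missing
  mass (e.g. 1/69 HC) reproduces subjects with no follow-up, whose
  missingness mechanism the source does not explain;
* MMSE and CDR-SOB follow per-group linear slopes plus noise (MMSE
  clamped to 0–30 integers); SUVR is drawn per analysis group around the
  1.5 amyloid-positivity threshold.

What the generator does **not** emulate: measurement noise structure of
real segmentation pipelines, site/scanner effects, non-normal feature
distributions, age/sex effects on morphometry, and informative dropout.
Passing tests therefore demonstrate correctness of the algorithms under
the stated generative assumptions, not clinical performance on real data.

The default 187-feature schema (68 Desikan-Killiany cortical thicknesses,
68 cortical volumes, 51 subcortical volumes) ships as a text resource.
The cortical roster is the standard 34-region parcellation per
hemisphere; the 51-structure subcortical roster is a package default (the
standard 45 whole-brain segmentation rows plus bilateral cerebral white
matter, cerebral cortex and lesion labels), since segmentation softwares
differ in which rows they report. Any schema of length ≥ 2 can be
substituted; the algorithms are dimension-agnostic.

## Follow-up validation

Terminal outcomes use the rule: the first visit whose diagnosis is worse
than the baseline category (HC = SMD < MCI < dementia, where dementia
covers AD and other dementias) or death, whichever comes first, is the
event, dated at that visit's month — no interval-midpoint imputation.
HC↔SMD moves and reversions are not events; stable subjects are censored
at their last attended visit; subjects with only a baseline visit count
as missing and are excluded from progression denominators (hence
denominators of 68, 74 and 11 when records are reconstructed from the
published counts). Progression percentages and ratios are reported to one
decimal, rounding half away from zero, matching the printed precision of
the source; the ratio is computed from unrounded proportions.

Kaplan-Meier curves and the two-group log-rank test are delegated to the
`survival` package behind the package's own interface, and the
Benjamini-Hochberg adjustment to `stats::p.adjust`; the test suite pins
both to independent naive oracles (explicit product-limit and
observed-minus-expected computations, direct step-up enumeration).

## Numerical choices and degenerate inputs

* Norm guards at 1e-12: a zero `Xᵀy` norm raises a no-covariance error; a
  vanishing orthogonal weight norm stops component extraction.
* The fit is closed-form per component (no iteration is needed for a
  single response), so there are no convergence parameters.
* Indices are not clipped to [0, 1]; clipping would destroy monotonicity
  diagnostics. The tie at exactly the 0.5 cutoff goes to the AD-like
  class, a deterministic and practically measure-zero rule.
* Single-class labels, fewer class members than folds, non-positive ICV,
  zero ICV variance, schema misalignment, and training/target subject
  overlap all raise specific errors rather than propagating silently; the
  overlap guard can be overridden for training-set diagnostics.
* Model files are versioned JSON written at maximum double precision;
  round-trip agreement is at the last-ulp level (~1e-16 relative).

## Problem sizes used in the checks

The bundled tests and the acceptance script run the full study-sized
problem (238 subjects × 187 features) for single fits and the
seed-replicated checks (20 seeds for subtype recovery, 5 seeds for Q²),
and smaller matrices (n ≤ 60) for the algebraic oracle comparisons, which
are scale-free. These sizes make the whole suite complete in a few
minutes on one CPU while leaving the statistical conclusions unchanged.

## Known limitations

* One predictive component only; multi-class discrimination is out of
  scope.
* The severity index is not a calibrated probability; 0.5 is a coding
  midpoint, not an estimated decision boundary.
* The generator's exchangeable correlation understates the anatomical
  covariance of real morphometry, which typically inflates orthogonal
  variation; on real data more orthogonal components may be selected.
* Whether projected indices should come from the refit full model (the
  default here) or from fold models is not settled; the full-model choice
  matches the "projected as unseen data" description and keeps the index
  a deterministic function of one model object.
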