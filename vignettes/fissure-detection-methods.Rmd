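---
title: "Detecting and localizing annular fissures from disc texture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and localizing annular fissures from disc texture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fissuremap)
```

## The problem

Outer annular fissures — tears of the annulus fibrosus (AF) reaching its
outer third — are a suspected source of chronic low back pain, but they are
largely invisible on conventional T2-weighted MRI. The only conventional MR
marker, the high-intensity zone (HIZ), misses roughly a third of fissures.
The reference standard, CT discography, is invasive. `fissuremap`
implements a non-invasive alternative: texture features computed from the
segmented disc on midsagittal T2-weighted slices feed an ensemble of
shallow neural networks that (a) classifies the disc as fissured or not
and (b), through an occlusion sweep, localizes the image columns whose
texture drives that classification.

## Pipeline overview

1. **Input**: per disc, a small image stack (five midsagittal slices by
   default) with a binary disc mask, grouped by patient. The package ships
   a phantom generator so the full pipeline can be exercised and validated
   without patient data.
2. **Texture features** (`extractFeatures`): an IBSI-style engine computes
   first-order statistics, Geary's C, and grey-level co-occurrence
   (GLCM), neighbourhood grey tone difference (NGTDM) and grey-level
   dependence (NGLDM) matrix features under several slice/direction
   aggregation conventions. A fixed 22-feature registry
   (`featureRegistry("fissure22")`) collects the features sensitive to tissue
   near outer annular fissures; `featureRegistry("full")` expands every
   implemented family over all of its aggregation modes.
3. **Classification** (`trainEnsemble`, `runCrossValidation`): an
   averaging ensemble of shallow networks (input → 5 tanh units → 2-way
   softmax), trained by batch gradient descent with momentum and adaptive
   learning rate, evaluated by patient-level stratified 10-fold
   cross-validation.
4. **Attention mapping** (`computeAttentionMap`): a vertical occluding
   slab sweeps the disc column by column; the drop in the (out-of-fold)
   classifier score at each slab position is mapped back to the slab
   center, normalized, and thresholded into a highlighted region.
5. **Evaluation** (`diagnosticMetrics`, `rocAuc`, `mcnemarMidP`,
   `judgeLocalization`): confusion-table statistics and ROC for the
   classifier, an exact mid-p McNemar comparison against the HIZ marker,
   and a rule-based judgement of whether the highlighted region matches
   the true fissure position(s).

## The texture engine

All matrix features use Chebyshev distance 1: four unique in-plane
directions for 2D co-occurrence, thirteen for 3D, an 8-neighbourhood for
in-plane NGTDM and the 26-neighbourhood for 3D NGTDM/NGLDM. Intensities
are discretized to a fixed number of bins (default 32) over the masked
range; fixed-bin-number discretization is scanner-scale free, which makes
every level-based feature invariant to global intensity shifts and
rescalings. NGLDM uses coarseness `alpha = 0`. The six GLCM aggregation
conventions (`2Davg`, `2Dmrg`, `2DDmrg`, `2Dvmrg`, `3Davg`, `3Dmrg`)
merge co-occurrence counts before feature computation; slices or
directions contributing no valid voxel pair are excluded from averages.

The four co-occurrence features in the registry (difference average,
difference variance, contrast, dissimilarity) depend on the matrix only
through the grey-level difference distribution, so the engine accumulates
per-slice, per-direction difference histograms rather than full matrices;
the exported `glcmMatrix` builds the full normalized matrix for
inspection and testing. For a normalized symmetric matrix dissimilarity
equals the difference average — the test suite asserts this identity, and
checks every feature against brute-force pair enumeration on tiny ROIs.

Geary's C uses inverse physical-distance weights in millimetres. The
exact computation is quadratic in the number of masked voxels, so beyond
3000 voxels a seeded uniform subsample is used; the weight matrix is
precomputed once per mask, which makes re-evaluation under the occlusion
sweep (where only intensities change) a single matrix–vector product.
A constant ROI has undefined C; undefined features are imputed as 0 with
a warning so the classifier input stays dense.

## Training rule and its parameters

Each network member is trained by full-batch gradient descent with
momentum 0.9 on the cross-entropy of the softmax output (the loss that
pairs naturally with a softmax read-out). The learning rate adapts per
epoch: a step that grows the loss by more than 4 % is rejected (weights
reverted, momentum cleared, rate × 0.7); an accepted step that lowered
the loss scales the rate by 1.05. Weights are drawn uniformly within
±1/√fan-in from a per-member seed (`base seed + member index`), which is
the only difference between ensemble members; the ensemble prediction is
the arithmetic mean of member fissure probabilities. Features are
z-scored with training-set statistics (stored in the ensemble and applied
to new inputs) — unstandardized texture features differ by orders of
magnitude and would stall gradient descent.

Early stopping tracks a validation set every epoch and returns the
weights of the *first* epoch achieving the minimum validation loss. By
default that set is a stratified inner 20 % split of the training data;
`runCrossValidation(..., earlyStop = "heldout")` instead scores the
held-out fold itself. Both conventions are defensible readings of
"validation" in a 10-fold protocol; the inner split is the default
because it keeps the held-out fold strictly unseen. A `patience`
parameter (default `Inf`) can stop training once the validation loss has
not improved for that many epochs; it never changes the returned weights
when the optimum has already been visited.

Cross-validation is at patient level: a randomized greedy bin-packing
assigns whole patients to folds, largest positive-disc contributors
first, each to the fold currently most deficient in positives. This
spreads fissure-positive discs as evenly as patient granularity allows
(the fold-to-fold spread is bounded by the largest single-patient
positive count). Training rows are ordered by disc identifier, so results
depend only on which discs are in a fold, never on input order.

## Attention mapping

The occluding slab is a full-height, all-slice vertical band (default
width 5 columns) stepped one column at a time over every ROI column.
Occluded voxels are replaced by the mean of the original, unoccluded ROI
(`roi_mean`), which is neutral and idempotent; median and zero fills are
available. In the default `drop` mode the attention value at a column is
the *decrease* of the classification score when the slab hides that
column, assigned to the slab center; overlapping slabs therefore yield a
smooth profile with no extra averaging. The drop is measured on the
log-odds scale: once an ensemble is confident, probability differences
saturate to zero while log-odds differences still rank columns, and the
two scales order columns identically. Negative drops (occlusion *raising*
the score) are clipped to zero before the profile is min-max normalized
into an overlay; voxels at or above the 0.8 quantile of in-ROI overlay
values form the highlighted mask, and a flat profile yields an empty
highlight.

A localization judgement is `correct` when every true in-plane fissure
(ventral and/or dorsal) is hit by the highlighted region within a
3-pixel column tolerance *and* no highlighted component lies farther
than that tolerance from every fissure. Discs whose only fissure extends
laterally cannot be seen on midsagittal slices and are always judged
incorrect (`lateral_fissure`), as are discs the upstream classifier got
wrong (`misclassified`). Partial hits on double-fissure discs report
`missed_inferior_fissure`; highlights with no fissure within tolerance
report `extension_mismatch`, or `diffuse_degeneration` for end-stage
discs.

## The phantom generator

`generateCohort` draws per-disc labels and renders each disc:

* **Geometry**: an ellipse replicated over slices with mild per-slice
  shrinkage — a slab-acquisition stand-in that avoids full 3D anatomy.
  Columns run ventral (left) to dorsal (right).
* **Compartments**: a bright nucleus whose signal falls with the
  degeneration grade (grades 2–5, defaults 100/80/55/38 intensity units)
  blending into a darker annulus (30) over a smooth radial sigmoid. The
  smooth transition is a partial-volume analogue: in resolution-limited
  T2 imaging the nucleus–annulus boundary is not a voxel-sharp step, and
  rendering it sharp would hand short-range texture statistics a giant
  bilateral "edge" structure that swamps the fissure signal in both
  classification and attention mapping.
* **Fissures**: thin bright streaks (about two rows thick, all slices)
  running from the nucleus boundary into the outer third of the annulus
  at the labelled side(s). Streak intensity is an absolute bright-fluid
  reference (above any nucleus signal, the classical bright-zone
  criterion) plus `fissureContrast` noise standard deviations — default
  contrast 6, noise SD 5. Lateral fissures leave no in-plane footprint:
  the disc is labelled positive but its image and fissure mask show
  nothing, exactly the failure mode midsagittal imaging has.
* **Severely disrupted discs** (default 20 % of fissured discs) get
  diffuse outer-annulus brightening with no delimitable streak; they are
  excluded from attention mapping but remain in the classification arm.
* **Labels**: fissure prevalence 94/123; position mixture 4 % ventral,
  81 % dorsal, 12 % both, 3 % lateral; the HIZ surrogate flag is carried
  by 63 % of in-plane fissured discs (and 3 % of fissure-free discs as
  false flags), and a Dallas-style extension grade consistent with the
  presence label is recorded for the dichotomization step.

What the phantoms do *not* emulate: MR acquisition physics, vertebral
anatomy, segmentation error, partial fissure filling, or fissures that
are genuinely isointense. Every phantom fissure except the lateral ones
is in principle visible, so recovery results on phantoms bound what the
pipeline can do when the imaging contains the signal — they do not
certify performance on patient data, where fissure conspicuity is the
central difficulty.

## Numerical and reporting choices

* Discretization 32 bins; GLCM/NGTDM/NGLDM distance 1; NGLDM
  `alpha = 0`; Geary subsample cap 3000 voxels (seeded).
* Probability 0.5 is the decision threshold, with the boundary assigned
  to the positive class.
* Percentages are reported to one decimal, likelihood ratios to three;
  localization rates round to whole percent. The positive likelihood
  ratio at perfect specificity is reported as infinite rather than a
  number.
* The mid-p McNemar test is computed by exact binomial enumeration:
  `2 P(K <= min(b,c)) − P(K = min(b,c))` for `K ~ Bin(b + c, 1/2)`.
* All randomness is seeded: cohort generation, fold assignment, member
  initialization, inner splits and Geary subsampling each derive from an
  explicit seed, and the end-to-end report is byte-identical across
  reruns with the same configuration.

## Problem sizes used in validation

The test suite validates parameter recovery on a 201-disc, 67-patient
cohort (streak contrast 6, noise SD 5) with 50-member per-fold ensembles,
10-fold patient-level cross-validation, member training capped at 400
epochs with early-stop patience 60, and attention mapping judged on a
seeded 30-disc subset of the attention-eligible discs; the null
calibration uses 600 pure-noise feature vectors. These sizes were chosen
as the smallest at which the recovery criteria (out-of-fold AUC,
localization rate, chance-level null) are stable across seeds while a
full run stays comfortably interactive.

## Known limitations

* The 480-feature configuration of a full radiomics tool is represented
  by the registry's family × aggregation expansion (33 features), not a
  byte-level replication of any particular tool's list.
* Occlusion sweeps are one-dimensional (columns of the midsagittal
  plane): vertical position within a column is not localized, and
  lateral fissures are invisible by construction.
* Ensemble training is plain R; the default 1000-member ensemble of the
  original protocol is supported but slow — 20–50 members already give
  stable averages on phantoms.
* `diffuse_degeneration` judgements depend on the phantom's degeneration
  grade; on real data this failure mode requires a radiologist's reading.
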