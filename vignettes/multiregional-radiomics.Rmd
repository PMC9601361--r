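---
title: "Multiregional radiomic signatures from DCE-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiregional radiomic signatures from DCE-MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Estrogen-receptor (ER) and progesterone-receptor (PR) status guide subtype
assignment and treatment choice in breast cancer, but are assessed from
invasive biopsies. Dynamic contrast-enhanced MRI (DCE-MRI) — one
pre-contrast acquisition followed by eight post-contrast acquisitions —
captures the wash-in/wash-out behaviour of a contrast agent in and around
a lesion. `radsig` implements a complete pipeline that turns a 9-frame DCE
study into intratumoral, peritumoral and multiregional *radiomic
signatures* (logistic rad-scores) of receptor status, together with a
seeded synthetic cohort generator so that every stage is testable without
patient data.

# Pipeline

## Kinetic parametric maps

Each pixel's curve \(SI_0, \ldots, SI_8\) is summarized by six
semi-quantitative maps:

* \( \mathrm{MSI} = \max_i\,(SI_{i+1} - SI_i) \), \(i = 0..7\) (intensity units);
* \( \mathrm{SI_{slope}} = 100\,(SI_8 - SI_{mean})/SI_{mean} \), with
  \(SI_{mean} = (SI_1 + SI_2)/2\);
* \( \mathrm{E_{initial}} = 100\,(SI_1 - SI_0)/SI_0 \);
* \( \mathrm{ESER} = 100\,(SI_1 - SI_0)/(SI_2 - SI_0) \);
* \( \mathrm{E_{peak}} = 100\,(SI_{peak} - SI_0)/SI_0 \);
* \( \mathrm{SEP} = 100\,(SI_2 - SI_0)/SI_0 \).

Two readings of "the peak enhancement time point identified from the
time–intensity curve" are defensible: a single lesion-level peak or a
per-pixel peak. The singular phrasing of a lesion's time–intensity curve
suggests one curve per region, so the default takes the argmax of the
*region-mean* curve over \(t = 1..8\) and evaluates every pixel there;
`per_pixel_peak = TRUE` switches to per-pixel argmax. The MSI step range
includes the pre-contrast-to-first step (\(i = 0\)). Degenerate
denominators (\(SI_0 = 0\), \(SI_2 = SI_0\), \(SI_{mean} = 0\)) yield 0
and are flagged rather than dropped, so ROI size is identical across maps.
Maps are computed over the whole raster in one pass per region (the filter
banks need context outside the ROI); the region only fixes the shared peak
timepoint.

## Segmentation

The lesion is segmented semi-automatically on a subtraction image
(post-contrast minus pre-contrast, negative values retained): an Otsu
threshold (256-bin histogram; the bin edge maximizing between-class
variance, ties broken toward the lower edge) is computed inside a
user-supplied seed box, and the mask is the largest 8-connected
supra-threshold component with holes filled. Which subtraction frame the
readers segmented is not knowable from a method description alone; the
default rule picks the timepoint with maximum mean enhancement inside the
seed box, and the timepoint is overridable. The peritumoral region is the
set of pixels within a 4 mm Euclidean radial distance of the lesion
(computed from an exact distance transform, mm converted to pixels by
rounding: 4 mm at 0.332 mm/px → 12 px), minus the lesion, clipped to the
breast mask. Euclidean rather than geodesic distance is used near
concavities — with a 4 mm radius and smooth lesion boundaries the two
rarely differ, and Euclidean dilation is the standard reading.

## Feature bank

For each of the 2 regions × 6 maps, intensities inside the ROI are clipped
to \(\mu \pm 3\sigma\) (ROI mean and SD) and quantized to 8 bits (256
levels, rounding half up); a constant ROI maps to level 128 and is
flagged. Four families are then extracted per (region, map) pair:

* **First-order (15)** on the quantized levels: mean, median, min, max,
  range, SD, variance (both with \(n-1\)), skewness \(m_3/m_2^{3/2}\),
  kurtosis \(m_4/m_2^2\) (non-excess), energy, entropy (bits, 256-bin
  histogram), uniformity, RMS, mean absolute deviation, IQR.
* **GLCM (60)**: symmetric, normalized co-occurrence matrices at distance
  1 in four directions (0°, 45°, 90°, 135°), restricted to pixel pairs
  entirely inside the ROI; 15 Haralick descriptors per direction, reported
  per direction (not direction-averaged).
* **Laws (100)**: all 25 5×5 masks from outer products of L5/E5/S5/W5/R5;
  responses of the ROI-z-normalized map, texture energy = |response|
  smoothed by a 15×15 mean filter; mean, SD, skewness, kurtosis within the
  ROI.
* **Gabor (240)**: DC-free complex filters at wavelengths 2, 4, 6, 8, 10 px
  × 8 orientations (22.5° steps), \(\sigma = 0.5\lambda\), isotropic
  envelope; ROI magnitude summarized by mean, SD, skewness, kurtosis,
  energy and entropy (bits, 32 bins).

That yields 15 + 60 + 100 + 240 = 415 features per (region, map) and
exactly 2 × 6 × 415 = 4980 per case. The bank's printed total is the
binding constraint; the per-family split is this package's convention,
with block-structured names (`{region}_{map}_{family}_{feature}`) so any
family can be swapped out. Laws and Gabor operate on the continuous
z-normalized map rather than the 8-bit levels: filter banks on quantized
data alias, while first-order and GLCM are defined on the levels. All
convolutions use symmetric (reflect) boundary padding; ROI statistics are
ROI-restricted.

Features are z-standardized column-wise using the *training* rows only
(sample SD, \(n-1\)); zero-SD columns are set to 0 and flagged.

## Signature construction

The cohort is split temporally 4:1 (first 80% of acquisition order train,
the rest validate) — a time-based, not random, split. Selection then runs
on training rows only:

1. **ICC filter.** Features are recomputed from a second reader's
   segmentations on a subset of cases; per-feature ICC(2,1) — two-way
   random effects, absolute agreement, single rater, the standard choice
   for inter-reader reproducibility when the variant is unspecified — and
   retention at ICC > 0.8.
2. **t-test.** Per-feature two-sided Welch test (the safer default when
   "two-sample t-test" is unqualified; a pooled-variance option exists),
   retaining p < 0.1.
3. **LASSO.** L1-penalized logistic regression; λ minimizes the 10-fold
   cross-validated binomial deviance on seeded, label-stratified folds
   (`lambda.min`; a 1-SE rule is available by flag since the choice is
   unstated). Survivors are the nonzero coefficients.
4. **Backward stepwise AIC.** Repeatedly drop the feature whose removal
   most decreases AIC (\(2k - 2\log L\)); AIC ties are broken by dropping
   the feature with the largest Wald p-value; stop at a fixed point.

A plain logistic fit on the survivors gives the rad-score (linear
predictor). The multiregional signature pools the selected intratumoral
and peritumoral features (deduplicated) and repeats LASSO + stepwise +
logistic fit. Selection survivor lists are nested by construction
(stepwise ⊆ LASSO ⊆ t-test ⊆ ICC), and the training-only inputs of every
stage are checksummed so that absence of validation leakage is verifiable.

## Evaluation

AUC is the trapezoidal area under the empirical ROC curve (equivalently
tie-corrected Mann–Whitney), with 95% DeLong confidence intervals and a
seeded 2000-rep bootstrap fallback for degenerate variance cases.
Sensitivity and specificity are reported at the threshold maximizing
Youden's J on the training cohort, then held fixed on the validation
cohort; because published per-cohort operating points sometimes suggest
re-optimization, a per-cohort-Youden mode is provided
(`per_cohort_youden = TRUE`). The report grid covers 2 endpoints × 3
scopes × 2 cohorts (12 cells). Training AUC is *not* constrained to
exceed validation AUC; the inversion is legitimate and occurs.

# The synthetic cohort generator

One representative 2D slice per patient (matching a 2D analysis), 128×128
px at 0.332 mm/px (a 340 mm field of view on a 1024 matrix). Each study
holds an elliptical lesion (semi-axes 8–16 px, i.e. roughly 5–11 mm),
inside a large elliptical breast-parenchyma region, with

\[ SI(t) = SI_0\,[1 + A\,(1 - e^{-\alpha t})\,e^{-\beta t}] + \varepsilon \]

per pixel — an empirical wash-in/wash-out form chosen deliberately over
pharmacokinetic (Tofts) modelling, since the analysis is semi-quantitative
and the six maps only need distinguishable wash-in/plateau/wash-out
regimes. Defaults: baseline \(SI_0 = 100\) (arbitrary units),
multiplicative smooth texture (correlation length 4 px, amplitude 0.15),
additive Gaussian noise SD 5, ER-positive lesions
\(A = 2.6,\ \alpha = 1.4,\ \beta = 0.08\) versus ER-negative
\(A = 2.0,\ \alpha = 0.9,\ \beta = 0.04\) (between-patient SDs 0.4, 0.25,
0.02), parenchyma amplitude 0.25. ER marginal prevalence 0.66 and PR 0.63
with a joint odds ratio of 6, mirroring typical co-prevalence; kinetic and
rim contrasts are keyed to ER, so PR is predictable through the
association (and is accordingly the harder endpoint). These values were
fixed once as a realistic regime — lesion-to-parenchyma contrast far above
noise, class overlap large enough that signatures stay imperfect — and are
all overridable in `synthetic_config()`.

Two design points deserve emphasis because the μ±3σ quantization step
*removes purely multiplicative contrasts* within an ROI — any planted
signal must therefore live in the shape of the within-ROI distribution:

* **Intratumoral signal.** A smooth exponential-marginal random field
  scales the per-pixel wash-out rate \(\beta\) by a class-dependent
  heterogeneity factor \(h\) (positive 0.60, negative 0.10). Early frames
  are barely affected, so the segmentation (driven by early enhancement)
  stays class-neutral; late frames acquire a skewed within-lesion
  distribution that first-order and texture features detect. Planting the
  signal in an amplitude field instead was rejected: it biases the Otsu
  boundary class-dependently and contaminates the peritumoral ring with
  lesion pixels, which breaks the controlled-rim property below.
* **Peritumoral signal.** The rim (4 mm wide) enhances in patches: a
  smooth field is thresholded so a fraction of rim pixels enhance at
  amplitude 0.35 of a class-neutral draw, and `peritumoral_effect`
  scales that fraction (default 0.45 base, +35% in ER-positive cases).
  At `peritumoral_effect = 0` the rim is *exactly* label-independent, so
  a peritumoral-only signature must be uninformative — a property the
  test suite asserts across seeds.

The simulated second reader perturbs a mask by adding a smooth, seeded
random field to its signed Euclidean distance transform and
re-thresholding — bounded boundary erosion/dilation with connectivity
preserved. No inter-reader noise magnitude is documented for this kind of
data, so the default jitter of 2 px is a free parameter chosen to give
ICC values spread around the 0.8 retention threshold.

What the generator does **not** emulate: 3D volumes, anatomy
(ducts/vessels/chest wall), k-space or acquisition physics, motion,
B1/T1 bias, multi-focal lesions, and scanner batch effects. Passing tests
therefore show that the pipeline machinery is correct and that its
statistical behaviour (null calibration, signal recovery, no leakage) is
sound — not that the published effect sizes transfer to real patients.

# Problem sizes and numerical choices

The test suite runs cohort-level suites with the first-order family only
(180 features/case): the planted signals are distribution-shape signals
that first-order statistics capture, and this keeps repeated-seed cohort
simulation fast; the full 4980-feature bank is exercised on single cases.
Chosen sizes: recovery suite n = 300 patients × 10 seeds at generator
defaults; null suite: two n = 400 cohorts × 10 label permutations each
(permutation destroys any genuine association while preserving the
feature distribution, and the larger validation side keeps the null AUC
band tight); controlled-rim property n = 100 × 10 seeds. The acceptance
script runs one n = 250 cohort end-to-end, with a 40-case second reader
feeding the ICC filter.

Other numerics: half-up rounding for quantization; entropy base 2;
sample (n−1) variance throughout; Otsu ties toward the lower edge;
8-connectivity for components; GLCM restricted to in-ROI pairs, a
direction with no pairs contributing zeros (flagged); glmnet warnings on
saturated small-λ path segments suppressed as benign; logistic fits with
|coefficient| > 15 flagged as near-separation; master seed fans out to
per-patient substreams via a fixed integer recurrence, so any study can be
regenerated independently of the cohort.

# Known limitations

* Single-slice analysis; a volumetric extension would change feature
  definitions (3D GLCM offsets, 3D filter banks).
* The per-family feature inventory is a package convention pinned only by
  the 415-per-block total; swapping in a different bank changes selected
  features but not the pipeline contracts.
* Stepwise elimination refits a logistic model per candidate removal;
  for very large survivor sets this is the slowest stage.
* DeLong intervals are asymptotic; very small validation sets fall back
  to the seeded bootstrap.
* The generator's ER-keyed signal makes PR performance derivative of the
  ER–PR association; it does not model PR-specific biology.

# A worked run

```{r, eval = FALSE}
library(radsig)
cfg <- synthetic_config(n_patients = 100, seed = 7)
cohort <- generate_cohort(cfg)
tab <- build_feature_table(cohort, families = "firstorder")
er <- vapply(cohort, function(s) s$er_label, 0L)
split <- split_cohort(cohort)
run <- run_endpoint(tab, er, split, endpoint = "ER", seed = 7)
evaluate_endpoint(run, er)
```
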