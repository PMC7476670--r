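---
title: "Two-stage weakly supervised slide classification with region correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage weakly supervised slide classification with region correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Nuclear BAP1 (nBAP1) expression in uveal melanoma is a strong prognostic
marker, normally read from immunohistochemistry or genetic testing. The goal
of this package is the computational counterpart of reading it directly from
routine H&E histology: predict a binary slide-level molecular label from a
whole-slide image, given only slide-level ground truth. Because a slide is
orders of magnitude larger than anything a CNN ingests, the slide is reduced
to fixed-size tumor tiles, every tile inherits its slide's label (a *weak*
label — correct in aggregate, wrong for some tiles), and slide-level answers
are reassembled from tile-level posteriors.

The method has two stages:

1. **Independent patch classification.** Non-overlapping windows with more
   than 90% tumor content are cropped, resized to a common input size, and
   classified by a residual CNN (ResNet-18 layout) trained with
   class-weighted cross-entropy, the weight of each class inversely
   proportional to its share of the training patches
   (`w_pos = N / (2 n_pos)`, `w_neg = N / (2 n_neg)`; mean per-example
   weight 1, and `w_pos n_pos = w_neg n_neg`).
2. **Region correlation.** Neighboring tumor patches tend to share class
   status. The patch network's pooled feature vectors (512-dimensional at
   full width) are re-assembled into a per-slide *global feature map* at
   their grid locations (zeros elsewhere), and a U-Net style
   encoder-decoder refines them into a per-cell probability map. The loss
   is gated by an element-wise product with the tumor mask, so off-tumor
   cells contribute exactly zero; the slide posterior is the arithmetic
   mean of the tumor-cell posteriors.

Five models are trained in a 5-fold slide-level cross-validation (patches of
one slide never straddle the train/validation boundary) and their posteriors
are averaged into an ensemble.

## The network engine

No deep-learning framework is attached: the package carries a compact
neural-network engine written on top of R's BLAS — im2col + GEMM
convolutions (with a cached sparse scatter operator for the backward pass),
batch normalization, max pooling, global average pooling, nearest-neighbour
upsampling, and SGD with momentum 0.9 and weight decay 5e-4. Every backward
pass is exact and checked against central finite differences in the test
suite (tolerances around 1e-6 on gradients of order 1). This keeps the whole
pipeline runnable and testable on one CPU with no external weights.

Training defaults follow the reference protocol: the patch classifier for 30
epochs from learning rate 0.001, divided by 5 at the start of (0-based)
epochs 10 and 20; the region model at a constant 0.0001 for 100 epochs; both
with momentum 0.9 and weight decay 0.0005. Desk-scale runs (below) use fewer
epochs and a larger rate because they train from random initialization
rather than fine-tuning pretrained weights.

Two reading notes on the loss functions:

* The patch loss normalizes by the summed weights of the batch, so its
  magnitude is comparable across imbalance levels.
* The region loss normalizes by the summed weights over tumor cells. Since
  all tumor cells of one slide share the slide label, the class weight
  cancels *within* a slide when slides are optimized one at a time; the
  weights still matter for any batching across slides.

## Checkpoint selection

Both stages keep the epoch with the best validation performance. For the
patch stage that is validation patch AUC. For the region stage the primary
metric is validation slide-level AUC; because a handful of validation slides
saturates that metric within a few epochs, ties are broken by validation
patch-level AUC, which keeps the epoch whose probability maps are best
calibrated rather than the first epoch that happens to rank a few slides
correctly.

## The synthetic slide generator

Real cohorts of labeled whole-slide images cannot ship with a package, so
every stage is exercised against a seeded generator whose ground truth is
known exactly:

* **Textures.** Each class (positive, negative, background tissue) is a base
  color plus Gaussian pixel noise plus darker elliptical "nucleus" blobs at
  a class-specific density. The two tumor classes differ in base color and
  blob density, so a mean-color linear classifier already separates clean
  tiles (AUC > 0.95 in the tests) — the pipeline always has signal to learn.
  The parameters are free choices documented in `default_textures()`; no
  claim of H&E realism is made, and results on synthetic cohorts do not
  certify performance on real stains, scanners, or morphology.
* **Tumor mask.** A star-convex random blob (radius perturbed by low-order
  sinusoids) covering 20-70% of the slide; star-convexity guarantees a
  single 4-connected component.
* **Heterogeneity.** Real tumors are not uniform, and the weak labels are
  wrong for some tiles. The generator renders a fraction
  `heterogeneity_rate` of each slide's tumor tiles with the *opposite*
  class texture. The flipped subset is spatially coherent: a stationary
  Gaussian random field is simulated on the tile grid (padded white noise
  smoothed with a full Gaussian kernel, so no edge artifacts), and the
  top-`rate` fraction of the field *ranked within the slide's own tumor
  tiles* flips. Ranking within the slide keeps every slide's label
  informative (a `1 - rate` majority always remains — the reason rates
  of 0.5 and above are rejected), while the field's correlation makes the
  noise locally coherent, which is precisely the structure the region
  stage exists to exploit. `heterogeneity_smoothness` is the field's 1/e
  autocorrelation distance in tiles (kernel sigma = smoothness / 2).
* **Scanner domains.** Training and test cohorts can come from different
  "scanners", emulated as a global affine color transform (diagonal channel
  gains plus an RGB offset, clamped). This is the simplest stand-in for
  systematic platform color differences; it does not model resolution,
  focus, or compression differences.

Per-slide seeds are derived deterministically from the cohort seed, so any
slide can be regenerated bit-exactly from its manifest row.

## Augmentation

Training patches are randomly cropped (256 to 224 at full scale), flipped
horizontally and vertically with independent probability 0.5, and
color-jittered with brightness/contrast/saturation factors drawn uniformly
from [0.6, 1.4]. A multiplicative range cannot apply to hue (an angle), so
hue is shifted additively by a draw from the same relative range scaled by
0.1 of the hue circle — an approximation, documented as such, and never
tuned. The order of the four jitter operations is randomized per call.
Evaluation uses a deterministic center crop and no color change.

## Evaluation

AUC is computed by the Mann-Whitney rank identity (ties counted 1/2), which
the tests verify against brute-force pairwise enumeration. Confidence
intervals use a stratified percentile bootstrap (positives and negatives
resampled separately, 2000 resamples by default), chosen because it applies
uniformly at patch and slide sample sizes; no claim is made that this
matches any particular analytic method. Threshold metrics (accuracy,
sensitivity, specificity, precision, F1) use the strict rule "positive iff
p > 0.5"; a posterior exactly at 0.5 is classified negative. Probability
maps render grey (negative) to blue (positive) at tumor cells and white
elsewhere.

Fold construction is stratified randomization under two invariants: fold
sizes differ by at most one and per-fold positive counts differ by at most
one (for the reference 66/74 cohort: five folds of 28 slides with 13 or 14
positives each).

## Desk-scale study conditions

The built-in experiment (`experiment_config()`, also behind
`scripts/acceptance.R` and the heavy acceptance tests) uses: 20 + 20
training slides and 4 + 4 test slides from the shifted scanner domain;
512 px slides with 64 px tiles (8 x 8 grids); heterogeneity 0.3 at
correlation length 3; tiles resized to 32 and cropped to 28; the slim
backbone (width 1/4, feature dimension 128) for 5 epochs at learning rate
0.01; a depth-2, 16-channel U-Net for 30 epochs at 0.01; 5 folds; 500
bootstrap resamples. These sizes keep a full 5-fold run around three
minutes on one CPU while leaving the qualitative structure intact:
independent patch AUC is capped by the 30% weak-label noise, and the region
stage recovers most of that gap by exploiting spatial coherence.

## Degenerate inputs and numerical choices

* An all-zero tumor mask yields an empty patch grid with a warning when
  tiling, and a zero loss with a warning in the region loss (the slide is
  skipped in training).
* Patch selection is strict (`ratio > 0.9`); a window at exactly the
  threshold is excluded. Windows smaller than `patch_dim` at slide edges
  are discarded.
* Resizing is exact area averaging (interval-overlap weights); constants are
  preserved bit-for-bit up to floating point, and upscaling requires an
  explicit flag.
* Global feature maps are zero-padded symmetrically (extra row/column going
  to the bottom/right) to the next multiple of `2^depth`; padding is
  recorded and removed from predicted maps.
* Probabilities inside cross-entropies are clamped to [1e-12, 1 - 1e-12].
* Batch normalization uses biased batch variance, running-statistic momentum
  0.1, and eps 1e-5; inference uses running statistics only, so predictions
  are batch-size independent.

## Known limitations

* The synthetic generator tests the *mechanism*, not histology: passing
  tests demonstrate the pipeline's correctness and its ability to exploit
  spatially coherent label noise, nothing about real-world diagnostic
  performance.
* The feature extractor is frozen during region training (two-stage
  protocol); end-to-end fine-tuning is out of scope.
* Pretrained backbone weights are optional user input; nothing is
  downloaded, and desk-scale runs start from He initialization.
* The pure-R engine is sized for desk-scale experiments; full-scale cohorts
  (hundreds of thousands of 224 px patches) call for a GPU framework, for
  which this package's protocol serves as the reference semantics.
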