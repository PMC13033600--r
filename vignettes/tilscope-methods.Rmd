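---
title: "tilscope: models, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tilscope: models, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantifying tumor-infiltrating lymphocytes (TILs) on H&E-stained lung
adenocarcinoma sections requires three nested delineations: where the tissue
is (versus glass), where the tumor parenchyma is (versus supporting stroma),
and where the individual lymphocytes are inside that stroma. `tilscope`
implements this three-stage pipeline as a tested library: a deterministic
tissue-contour stage, a small nested-U convolutional segmenter for
parenchyma, a compact single-stage anchor-based detector for lymphocytes,
per-high-power-field (HPF) counting with categorical grading, and the
inter-rater agreement battery used to compare automated counts with expert
counts (ICC, Cohen's and Fleiss' kappa, Bland-Altman).

Because slide archives cannot ship with a package, every stage is validated
against a seeded synthetic-histology generator with exact ground truth. This
vignette records the models, the defaults and why they are what they are,
and what the synthetic validation does and does not demonstrate.

## Stage 1: deterministic tissue contours

`segment_tissue()` works on a thumbnail at 2.5x objective resolution
(`make_thumbnail()`, exact area averaging). Two independent channels are
combined by a logical AND:

* **Edge channel** — grayscale, Roberts cross magnitude (L2 combination of
  the two diagonal kernels), Otsu binarization over the 256-bin histogram,
  then morphological closing: 3 dilation passes followed by 3 erosion passes
  with the 3 x 3 cross (the discrete disc at that size). Stained tissue is
  strongly textured at low power, so the edge channel responds *inside*
  tissue, not only at its rim; Otsu then separates textured tissue from the
  near-uniform glass, and closing fills the interior holes.
* **Color channel** — HSV gate for H&E pink/purple: hue 18-180 on the 0-180
  half-degree scale, saturation 9-255, value 0-255 (glass is excluded because
  pure white has zero saturation), cleaned with a binary median filter of
  radius 4.

Numerical conventions worth stating: "closing performed three times" is
implemented as iterated dilation then iterated erosion, since a literal
repeat of one closing is a no-op (closing is idempotent); erosion treats
pixels beyond the frame as foreground so the closing is extensive on the
finite frame; Otsu ties break toward the lowest threshold; the binary median
uses clipped windows at the border with a strict-majority rule. Small-
component suppression is available (`min_area`) but off by default, keeping
scattered small tissue fragments. Component outlines are polygonized with
contour tracing at level 0.5; holes inside a component produce additional
rings, a documented limitation.

## Stage 2: parenchyma segmentation

`build_u2netp()` constructs the small nested-U architecture: six encoder
stages of residual U-blocks with heights 7/6/5/4 plus two dilation-only
blocks (dilations 1/2/4/8), mirrored decoder stages, mid-channel width 16,
stage width 64, one 3 x 3 side output per decoder level and a 1 x 1 fusion
convolution over the six side maps. The default build has exactly 1,131,181
trainable parameters (1.13 M to two decimals), counting convolution weights,
biases and the normalization affine pairs; `param_count_millions()` guards
this budget against architectural drift. Side-output fusion can be modulated
by a parameter-free attention gate (softmax-normalized per-map mean
confidence, treated as constant in the backward pass); it adds no parameters
and defaults to on.

The training objective is the composite loss

L_total = alpha * L_WBCE + beta * L_Dice

with weighted binary cross-entropy (positive-class weight `w`, predictions
clipped to [1e-7, 1 - 1e-7] before the logarithms) and Dice loss with
smoothing eps = 1e-6 in numerator and denominator. The term weights are not
dictated by the method; the package defaults to alpha = beta = 1 and w = 1,
all configurable. Training uses AdamW (beta1 0.9, beta2 0.999, eps 1e-8),
initial rate 1e-4, cosine annealing with T_max = 50, patch size 640, batch
16, at most 300 epochs with early stopping at patience 20 on validation
Dice (F1 breaks ties) — these canonical defaults sit in
`seg_train_config()`.

Inference (`predict_parenchyma()`) resamples the image to 5x-equivalent
resolution using the `magnification * mpp = 10` scanner relation, tiles with
overlap-averaged probabilities, thresholds at 0.5 and returns the mask at
source resolution.

### The neural-network core

No deep-learning framework is available to R here, so the package carries a
small tape-based autodiff core (`R/nn.R`): im2col convolution on BLAS
matmuls, batch normalization, (leaky) ReLU, max pooling, linear-operator
resampling, AdamW and SGD with momentum, and a cosine schedule. Gradients
are verified against central finite differences in the test suite (relative
agreement better than 1e-4 on a 4 x 4 case). Normalization statistics are
computed per sample during training (batch size is small) while running
averages serve inference — the standard train/eval split of batch
normalization.

## Stage 3: lymphocyte detection

`build_detector()` is a compact single-stage anchor-based detector: a small
strided-convolution backbone to strides 8/16/32, a top-down pathway merging
coarse semantics into fine maps, a bottom-up pathway re-aggregating them,
and a decoupled head per scale (separate classification and box/objectness
branches), three anchors per cell. The loss is the paper-family composition:
binary cross-entropy for classification (assigned anchors), binary
cross-entropy for objectness (all anchors), and Complete IoU for box
regression (assigned anchors only):

L_CIoU = 1 - IoU + rho^2 / c^2 + alpha * v

with rho the center distance, c the enclosing-box diagonal,
v = (4/pi^2)(atan(w_gt/h_gt) - atan(w/h))^2, and
alpha = v / ((1 - IoU) + v) — the standard completion of the weighting
function, with alpha treated as a constant in the gradient. Box decoding is
the bounded sigmoid decode (center offset in (-0.5, 1.5) cells, size in
(0, 4) anchor units). Anchor defaults form size bands: single-cell
anchors (6/9/12 micron diameters at the configured `mpp`) on the stride-8
head and small/large aggregate scales on the coarser heads, so the
size-ratio assignment rule ([1/4, 4]) naturally routes single cells to the
fine head. Assignment targets the grid cell containing the box center
(half-open convention); during training the two nearest neighbor cells are
also supervised, which densifies the gradient without changing the exported
assignment contract. Post-processing is greedy NMS (confidence descending,
ties by index, suppression at IoU >= 0.45) followed by stroma gating
(detections whose center leaves the stromal mask are discarded — gating
after NMS).

Canonical training defaults (`det_train_config()`): SGD, initial rate 1e-2,
weight decay 5e-4, momentum 0.937, cosine annealing, 640-pixel inputs,
batch 8, 250 epochs. Two training aids matter at short schedules and are on
by default: class-balanced objectness with online hard-negative mining (the
3 x n_pos highest-scoring negatives carry most of the negative mass) and
per-term gradient gains (box term x 3). Both only reweight gradients; the
reported loss keeps the unit-weight composition.

## The synthetic-histology generator

`generate_scene()` renders, deterministically per seed: a white glass
background (245-255), pink stroma with spatially correlated cellular mottle
(block noise at 2- and 8-pixel scales plus fine grain — the texture real
tissue shows at low power, and what the edge channel keys on), darker purple
parenchyma blobs with stronger texture and nuclear speckles, and
lymphocytes as near-circular dark-blue discs with diameters drawn uniformly
from 6-10 microns, converted through `mpp`. Tissue and parenchyma geometry
are unions of random star-convex blobs rescaled toward the requested
coverage targets; the realized lymphocyte count is Poisson with mean
density x stromal area, placed uniformly on stroma. Scene invariants
(parenchyma inside tissue, cell centers on stroma) are asserted before
return.

What the generator does *not* emulate: nuclear chromatin texture, stromal
fiber anisotropy, tertiary lymphoid structure organization, staining
gradients, folds and pen marks, or the morphological ambiguity between
lymphocytes and tumor-cell nuclei that makes real detection hard. Passing
the synthetic battery therefore demonstrates that the machinery — losses,
optimization, decoding, suppression, counting, statistics — is implemented
correctly and can be trained end to end; it does not certify accuracy on
clinical slides.

## Desk-scale reference conditions

The package's self-validation runs at desk scale on one CPU
(`R/recipes.R`); sizes were chosen once as realistic-but-small study
conditions and are stated here as such:

* **Tissue stage**: 50 scenes, 384 x 384 at mpp 2 (5x-equivalent), two
  fragments covering about half the frame. Mean Dice against truth must be
  at least 0.95 and never below 0.90.
* **Segmenter**: tiny nested-U variant (3 encoder stages, mid width 4,
  stage width 8) trained on 64-pixel native-resolution crops of 14 scenes
  (96 x 96, tumor fraction 0.4), AdamW at 1e-3, up to 25 epochs. Held-out
  Dice (5 scenes, 128 x 128) must reach 0.85. Patches are cropped, never
  squeezed, so training and tiled inference see the same spatial statistics.
* **Detector**: light variant (width 4, one conv per backbone stage)
  trained on 24 scenes at 20x-equivalent resolution (mpp 0.5, cells 12-20
  px), two thirds dense aggregates (5000 cells/mm^2) and one third moderate
  (1200/mm^2), SGD at 2e-2 with momentum 0.9, 60 epochs of per-sample
  steps, flip augmentation. At this schedule length the optimization is
  bimodal — most runs collapse the objectness loss into a discriminative
  regime, an occasional initialization stays on the high-loss plateau — so
  the recipe scores each run's recall on a selection set of sparse scenes
  (separate from any held-out evaluation set), restarts with a derived seed
  (up to three attempts), and keeps the first run reaching selection recall
  0.85 or otherwise the best attempt. Pooled recall at IoU 0.5 over sparse
  held-out scenes (800 cells/mm^2) must reach 0.8.

The detector resolution choice deserves a note: at mpp 1.0 a lymphocyte is
smaller than one stride-8 grid cell and neighboring cells become
contradictory negatives, which a short schedule cannot overcome; at mpp 0.5
cells span 1.5-2.5 grid cells and training converges. This mirrors practice
— cell detectors run on high-magnification patches. At desk scale the
trained detector reaches high recall with moderate precision
(over-detection on textured stroma); absolute count agreement at the
published level is a cohort-scale property the desk models do not claim.

## TILs quantification and agreement

The stromal mask is `tissue AND NOT parenchyma`. `count_in_fields()` places
square windows of one HPF area (default 0.237 mm^2, a 22 mm field-number
eyepiece at 400x; the field area is configurable) at seeded random
stroma-covered positions and counts detections whose center lies in the
window and on stroma, boundaries inclusive. Grading uses the
`<100 / 100-300 / >300` cells-per-HPF cuts with both boundary values
belonging to "moderate".

Agreement statistics: ICC is the single-measures two-way random-effects
absolute-agreement form ICC(A,1) — single measures because raters are
compared individually — computed from the ANOVA mean squares with the
F-distribution confidence interval (McGraw & Wong 1996). Cohen's kappa
(pairwise) and Fleiss' kappa (overall) use seeded percentile bootstrap
intervals (2,000 resamples) since no closed-form interval is canonical for
small rater panels; a degenerate table (both raters constant and identical)
is reported as kappa 1 with a flag. Bland-Altman reports mean bias and
bias +/- 1.96 x sample SD. Strength labels follow Cicchetti (1994) for ICC
and Landis & Koch (1977) for kappa. Parameter recovery is tested by
simulation: with subject SD sigma_s and rater noise SD sigma_e the ICC
estimate must fall within 0.05 of sigma_s^2 / (sigma_s^2 + sigma_e^2) at
n = 200.

## Design choices that were genuinely open

* Five HPFs are placed at seeded random stroma positions; a hotspot mode
  (rater-chosen fields) would require a saliency definition the method does
  not provide.
* Hue jitter "±10%" is read as ±10% of the hue scale (±18 half-degrees);
  saturation and value jitter are multiplicative factors.
* The 70/15/15 split is at slide level with rounded validation/test sizes
  (each at least 1) and the remainder to train, so 20 slides split 14/3/3
  and 3 slides split 1/1/1.
* All-point interpolation for average precision (11-point available).
* Empty-versus-empty Dice is 1.0 (two raters agreeing nothing is present).
* Undefined metrics (zero denominators) are reported as NA with a flag,
  never silently as 0.
* Missing-region reconstruction is exposed as mask-guided nearest-neighbor
  inpainting (`inpaint_nearest()`) but applied nowhere by default.

## Known limitations

The synthetic scenes are color-separable, so desk-scale accuracy figures
are upper bounds on what identical machinery would achieve on real stains.
The detector's desk-scale precision is modest; counts from it overestimate
density on textured stroma. The nested-U forward pass in plain R is orders
of magnitude slower than a GPU framework, so canonical 640-pixel, 300-epoch
training is out of reach here by design; the recipes in `R/recipes.R` are
the supported desk-scale conditions.
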