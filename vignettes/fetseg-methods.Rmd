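---
title: "Methods: losses, weights, prompts and evaluation in fetseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: losses, weights, prompts and evaluation in fetseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(fetseg)
```

## The problem

Fetal head ultrasound planes are segmented into four classes: background,
fetal brain, the cavum septum pellucidum (CSP) and the lateral ventricles
(LV). The latter two are tiny — often a few dozen pixels in a 256 x 256
plane — and absent altogether in first-trimester views, so the class
distribution is severely imbalanced and ordinary Dice training neglects
exactly the structures that carry the most diagnostic weight. fetseg
packages the computational machinery used around a prompted segmenter for
this task: class-imbalance weighting, a combined weighted Dice + Lovász
loss, bounding-box prompt derivation, a nine-strategy augmentation
pipeline, and DSC/HD/ASD evaluation, all exercisable on synthetic
phantoms.

## The phantom generator

`generate_phantom()` emulates the *structure* of a fetal head plane, not
its physics: a dark background, a dominant bright ellipse (brain), and
two small darker rectangles strictly inside it — CSP near the midline,
LV lateral — plus multiplicative Gaussian speckle. The geometry is chosen
so that every sample satisfies the count ordering
`background > brain > CSP, LV`, which is the property all downstream
machinery depends on (inverse-frequency weights, box prompts, the
surrogate's features). Defaults: 256 x 256 images; ellipse semi-axes
27–38 % of the image side (keeping the ellipse under half the image
area so background always dominates); rectangle sides 3–7 % of the
side; speckle variance 0.02 in squared intensity units. 20 % of a
generated dataset omits CSP and LV, mirroring first-trimester planes.
Everything is a pure function of `(seed, index)`.

What the phantom does **not** model: speckle correlation, acoustic
shadowing, skull echoes, boundary ambiguity, anatomical shape variation.
Tests passing on phantoms therefore validate the *bookkeeping and
mathematics* of the pipeline — counts, losses, boxes, metrics, training
dynamics — not clinical segmentation performance.

`split_dataset()` uses floor-then-remainder rounding with the remainder
assigned to the test split; at n = 3832 under 0.6/0.2/0.2 this uniquely
reproduces the 2299/766/767 partition, with the one odd image landing in
test.

## Augmentation

`build_strategies()` returns the nine named strategies with their
constants (crop 128 from 256, flip and rotation probability 0.3,
rotation limit 30 degrees, random-resized-crop scale 1.2–1.4, advanced
set probability 0.5, elastic alpha 1 / sigma 50, noise variance 10–50 on
the 8-bit scale, blur kernel 3–7). Design choices where the constants
alone do not pin down an implementation:

* Each strategy emits exactly one output per input — forced by the
  9 x 2299 = 20 691 count. Probabilistic sub-transforms may no-op; the
  (resized) output is still emitted.
* Geometric transforms use bilinear resampling for images,
  nearest-neighbour for label maps, background fill for rotation
  borders: labels stay valid class indices and never interpolate.
* The combined strategy chains crop, both flips and rotation in that
  order with their individual parameters.
* The pad-and-crop strategy pads by 1/8 of the image side per side
  (reflection) before cropping back; the pad magnitude is a package
  choice, configurable.
* The random-resized-crop scale is applied to the 256 target and then
  cropped back to 256 (scale-then-crop).
* Strategy constants are parameterised by the target size
  (crop = size/2, pad = size/8) so the pipeline runs identically at
  reduced working resolutions; the toolkit's own test and demonstration
  runs use 32–64 px phantoms.

A note on the elastic transform: with alpha = 1 and sigma = 50 the
smoothed displacement field is sub-pixel (standard deviation of order
1e-3 px), so at these constants it is a near-identity on the image and
an exact identity on the nearest-neighbour-resampled label map. The
constants are kept as stated; the transform does its stated work only
with larger alpha.

## Class weights

`count_classes()` tallies pixels per class over a mask collection and
replaces zero counts by one. `compute_weights()` takes inverse
frequencies `total/counts`, normalises them by their sum and min-max
rescales into `[min_weight, max_weight]`:

w_c = (r_c − min r) / (max r − min r) · (max_w − min_w) + min_w

The "smoothing" step between normalisation and rescaling is undefined in
the source procedure; it is implemented as the identity, making the
step pure min-max rescaling. This is the central interpretation risk of
the module and is deliberately isolated in one function. Two further
choices: the degenerate all-counts-equal case returns the midpoint of
the range, and the default range `[0.1, 0.9]` brackets the illustrative
weight vector `[0.1, 0.1, 0.9, 0.7]`. On 100 phantoms the computed
weights come out at approximately `(0.10, 0.10, 0.90, 0.72)` — the same
small-small-large-medium shape.

Bounds, anti-monotonicity in counts and scale invariance are asserted
property-style against an independently coded transcription of the
procedure.

## Losses

**Weighted Dice.** The formula sums over *all* `C·H·W` one-hot entries,
each weighted by its class's weight:
`L = 1 − 2 Σ y p w / Σ (y + p) w` with an epsilon (default 1e-6) in
numerator and denominator. A per-pixel weight indexed by class is only
well defined over the one-hot expansion when a single scalar loss must
cover all classes, so the entry-weighted reading is the default; a
per-class-Dice-then-weighted-average variant is available via
`mode = "per_class"`. With uniform weights the default reduces exactly
to the standard soft Dice loss.

**Weighted Lovász.** Per class, the Lovász extension of the Jaccard loss
is evaluated on the class's error vector (errors sorted descending,
inner product with the discrete Jaccard gradient); class terms combine
as `Σ w_c ℓ_c / Σ w_c`. The softmax (per-class error vector) variant is
used since the task is 4-class. At hard binary predictions each class
term equals `1 − IoU` exactly — the property the test suite checks
against a brute-force set-arithmetic oracle. For a class absent from the
truth the extension evaluates to the class's maximum predicted
probability; this natural convention is kept as the default because it
is the only one that preserves the vertex property (with empty-truth IoU
read as zero for a non-empty prediction), and `absent_classes = "skip"`
drops such classes instead.

**Combined.** `L = α·L_Dice + β·L_Lovász`, both coefficients 0.5 by
default — equal contribution of the overlap-oriented and IoU-oriented
terms.

## Prompt boxes

For each class channel, pixels above the threshold (default 0.5 —
for binary one-hot channels any value in (0, 1) is equivalent) define a
tight `[x_min, y_min, x_max, y_max]` box, 0-based inclusive. The offset
is applied as *symmetric outward expansion* clamped to the image bounds:
the prompt-sensitivity study reads larger offsets as larger prompts, and
an inward or shift interpretation is incompatible with that. Classes
with no activated pixels map to the sentinel `[0, 0, 0, 0]`, and the
result always contains every class index. Tightness at offset 0 and
monotone nesting over offsets are oracle-checked.

## Evaluation

DSC is the set formula on class pixel sets. HD and ASD act on *border
point sets*: a class pixel is a border point iff a 4-neighbour lies
outside the class or the pixel touches the image edge. Distances are
Euclidean in pixel units (no physical spacing). ASD follows the printed
directed formula (prediction → truth); a symmetric variant is behind a
flag. Empty-set conventions, chosen to keep metrics finite and
monotone: both regions empty → DSC 1, HD 0, ASD 0; exactly one empty →
DSC 0, HD and ASD equal to the image diagonal.

The `mean` row of a report is the unweighted arithmetic average over all
classes *including background*: that convention — and no other — makes
the four published per-class scores of the prompted model average to its
headline triple (0.90117 DSC, 1.86484 HD, 0.46645 ASD) to five decimals,
which the acceptance suite verifies.

## Training harness

The real prompted foundation-model fine-tune is out of desk scope; the
harness exposes a `predict_segmenter()` interface and ships a surrogate:
a per-pixel multinomial-logistic classifier over six features (bias,
intensity, intensity², and one box-indicator channel per structure
class). Because the model is linear in its 4 x 6 weight matrix, the
combined loss has a closed-form gradient (entry-weighted Dice
analytically; Lovász via its sorted-permutation subgradient; softmax
backward), verified against numerical differentiation to ~1e-9 in
development. The optimiser is hand-written AdamW — decoupled weight
decay, betas 0.9/0.999 — with learning rate and weight decay 1e-4,
MultiStepLR milestones [10, 20, 30] at gamma 0.7, and early stopping
with patience 5 on the validation combined loss (strict decrease counts
as improvement; `min_delta` configurable). Prompts are derived from the
ground-truth masks at offset 0 during training.

Problem sizes: the harness demonstrations train on 50 phantoms at
64 x 64 (30 train / 10 val after the 60/20/20 split) with batch size 1,
which gives the 30-epoch budget roughly 900 AdamW steps — enough for the
linear surrogate's argmax pattern to settle (mean phantom DSC ≈ 0.94;
the asymptotic fit at ~3000 steps is the same). The package default
batch size is 8; batch size is a free parameter of the harness, not a
quantity inherited from the study.

Two oracle segmenters support the prompt-offset ablation:
`"truth_in_box"` (truth inside each class's box, background outside) is
exactly right at offset 0 and can only stay equal or degrade as boxes
grow, giving the non-increasing mean-DSC direction; `"box_fill"`
(predicts each class over its whole box) degrades strictly with offset
and is the clearer demonstration of the published degradation pattern.

## Numerical and degenerate-input choices

* Argmax ties break toward the lowest class index (deterministic).
* One-hot masks are channel-first `C x H x W`; coordinates are
  row-major, y down, x right, 0-based, boxes inclusive.
* Dice epsilon 1e-6; equal-count weights → range midpoint; empty mask
  collections, negative counts, mismatched shapes and out-of-schema
  labels raise immediately with the offending value named.
* All randomness flows through one seed via deterministic child seeds
  per (stage, sample, strategy), so stages are independently
  reproducible and whole-pipeline reruns are bit-identical.

## Limitations

The phantom's simplicity means weight vectors, loss landscapes and
metric values here say nothing quantitative about clinical data; the
published per-model tables are reproduced only where they are pure
arithmetic (mean aggregation, split and augmentation counts). The
surrogate is a feature-engineered stand-alone model, deliberately far
smaller than any segmentation network; it exercises the training
machinery, not segmentation research. The Lovász loss's absent-class
convention and the Dice entry-weighting are interpretation choices
documented above and switchable; results with other conventions will
differ.
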