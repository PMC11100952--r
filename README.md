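# fetseg

Building blocks for prompt-based multi-class segmentation of fetal head
ultrasound planes. The segmentation target is four classes — background,
fetal brain, cavum septum pellucidum (CSP) and lateral ventricles (LV) —
where the CSP and LV occupy only a handful of pixels and vanish entirely
in first-trimester views. The package implements, as a tested library
plus a small CLI, the machinery such a pipeline needs around the
segmenter itself:

* a **seeded phantom generator** (bright brain ellipse, two small dark
  rectangles, multiplicative speckle) plus the 60/20/20
  floor-then-remainder dataset splitter;
* the **nine-strategy augmentation pipeline** (resize, crops, flips,
  rotation, their combination, random-resized-crop, pad-and-crop, and a
  brightness/elastic/noise/blur set), applied jointly to image and label
  map, expanding a dataset exactly 9-fold;
* **inverse-frequency class weights** smoothed into a range
  `[min_w, max_w]`:
  `w_c = (r_c − min r)/(max r − min r) · (max_w − min_w) + min_w`,
  where `r_c ∝ total/count_c` normalised to sum 1;
* the **combined loss** `L = α·L_Dice + β·L_Lovász` (α = β = 0.5), with
  an entry-weighted soft Dice
  `L_Dice = 1 − 2Σ y·p·w / Σ (y+p)·w`
  over the one-hot expansion and the per-class Lovász extension of the
  Jaccard loss combined as `Σ w_c ℓ_c / Σ w_c`;
* **prompt bounding boxes** per class from one-hot masks
  (`[x_min, y_min, x_max, y_max]`, threshold + symmetric outward offset,
  sentinel `[0,0,0,0]` for absent classes);
* **evaluation**: per-class and unweighted-mean DSC
  (`2|A∩B|/(|A|+|B|)`), symmetric Hausdorff distance and (directed)
  average surface distance over 4-neighbour border point sets;
* a **training harness** — AdamW (lr and weight decay 1e-4),
  MultiStepLR at epochs [10, 20, 30] with gamma 0.7, early stopping with
  patience 5 on validation combined loss — around a pluggable segmenter
  interface with a CPU-scale surrogate, plus the loss-variant and
  prompt-offset ablations.

## Worked example

Generate 50 phantoms at a 64 x 64 working resolution, split them
60/20/20, derive class weights from the training masks, train the
surrogate under the stated optimiser configuration, and evaluate:

```r
library(fetseg)

samples   <- generate_dataset(50, phantom_params(64, 64, seed = 11))
sp        <- split_dataset(50, seed = 11)
train_set <- samples[sp$assignment == "train"]
val_set   <- samples[sp$assignment == "val"]
sp$counts
#> train   val  test
#>    30    10    10

w <- compute_weights(count_classes(lapply(train_set, `[[`, "label_map")))
w
#> <class_weights> [ 0.10000, 0.10222, 0.90000, 0.68670 ] in [ 0.1 , 0.9 ]

cfg <- train_config(max_epochs = 30, batch_size = 1, seed = 11,
                    loss = loss_config(as.numeric(w)))
fit <- train(surrogate_segmenter(4, seed = 11), train_set, val_set, cfg)
fit
#> <train_result> 30 epochs run, best val loss 0.77338 at epoch 30

report <- evaluate_segmenter(fit$model, val_set)
report_table(list(surrogate = report))[, c("model", "mean_DSC", "mean_HD", "mean_ASD")]
#>       model mean_DSC mean_HD mean_ASD
#> 1 surrogate  0.94178 4.29999  1.07244
```

The computed weight vector has the small–small–large–medium shape
(background and brain near the lower bound, CSP at the upper bound, LV
in between) that inverse-frequency weighting produces on imbalanced
fetal-head data. The surrogate — a per-pixel softmax classifier over
intensity and box-prompt features — reaches a mean phantom DSC of 0.94:
good enough to exercise every part of the loss/optimiser/early-stopping
machinery, and nothing more.

Prompt boxes for one sample (class 0 is background, spanning the image;
boxes are 0-based inclusive `[x_min, y_min, x_max, y_max]`):

```r
boxes_from_label_map(samples[[1]]$label_map, prompt_config(offset = 0))
#> class 0: [0, 0, 63, 63]
#> class 1: [9, 5, 47, 51]
#> class 2: [29, 23, 31, 26]
#> class 3: [16, 28, 18, 30]
```

A shell entry point wrapping the same functions is installed at
`system.file("exec", "fetseg", package = "fetseg")` with subcommands
`phantom`, `augment`, `weights`, `boxes`, `evaluate` and `pipeline`.

## Package layout

* `R/` — schema and one-hot encoding, phantom generator and splitter,
  augmentation, class weights, losses, prompt boxes, metrics, surrogate
  and training harness, pipeline.
* `tests/testthat/` — unit and property tests with independent
  brute-force oracles (set-arithmetic IoU, prefix-set Lovász extension,
  pixel-scan boxes, all-pairs distances).
* `vignettes/fetseg-methods.Rmd` — the model choices, parameter
  conventions and their rationale.
* `inst/exec/fetseg` — the CLI wrapper.
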