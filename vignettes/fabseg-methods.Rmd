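---
title: "Methods: models, losses, metrics and the phantom generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, losses, metrics and the phantom generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fabseg)
```

This vignette is the package's own account of its methods: the network and
the reasoning behind each block, the loss and metric definitions, the
numerical conventions, what the synthetic phantoms do and do not emulate,
and the design choices made where more than one convention was defensible.

## The segmentation problem

Standard-plane fetal abdominal ultrasound asks for per-pixel labels over a
14-class schema (background + 13 structures) on grayscale images. The
difficulty profile is specific: structure sizes span two orders of
magnitude (a bladder vs. the umbilical artery inlet), organs are scattered
rather than contiguous, the thin vessels (inferior vena cava, umbilical
vein) have low contrast against surrounding tissue, and coherent imaging
superimposes multiplicative speckle. Each encoder block below addresses one
of these difficulties.

## Network

The model is a DeepLabv3+-style encoder–decoder. A small residual CNN
backbone (stage widths configurable; stem stride 2 plus three stride-2
stages, output stride 16; the stride-4 stage is tapped for low-level
features) feeds four feature-enhancement blocks in sequence, then a 1×1
compression:

backbone → ASPP → MSCA → BiFormer block → CCA → 1×1 conv.

The decoder upsamples the compressed features ×4 (bilinear, align-corners
off), adjusts channels with a 1×1 convolution, concatenates the low-level
features (reduced to a small width by a 1×1 convolution, DeepLabv3+
convention), refines with a 3×3 convolution, upsamples ×4 again, and a 1×1
classifier emits one raw score map per class. `predict_mask()` decodes by
per-pixel argmax with ties resolved to the lowest class id.

Block semantics, each of which is pinned by an oracle test:

* **ASPP**: four parallel same-padded 3×3 atrous convolutions, dilation
  rates 6/12/18/24. A 3×3 kernel at rate r has effective receptive field
  (2r+1)² (13², 25², 37², 49²); the tests verify the impulse-response
  support exactly and that each branch equals a dense convolution with a
  zero-inflated kernel to 1e-6. The block is linear (no internal
  activation); the network applies layer norm + ReLU after concatenation.
* **MSCA**: attention map = 1×1 channel mix of (5×5 depthwise aggregate +
  Σ strip branches), each branch a 1×k followed by a k×1 depthwise
  convolution (k = 7, 11, 21); output = attention ⊙ input. The strip pair
  equals one dense separable k×k convolution (tested to 1e-6). The branch
  order "1×k then k×1" and sum fusion before the channel mix are the
  conventional reading of the strip-attention design; no nonlinearity is
  applied to the attention map, so forcing a unit map recovers the input
  exactly.
* **BiFormer block**: x + DWConv3×3(x); then + BRA(LN(·)); then +
  MLP(LN(·)) with GELU. Inside BRA, tokens are partitioned into S×S
  regions; region-mean queries/keys give an affinity matrix; each query
  region attends only to tokens of its top-k key regions (softmax over the
  routed set, logits scaled by 1/√d per head). The routing hyperparameters
  are not pinned by any convention we could adopt blindly, so the defaults
  are deliberately safe: S = 2 and top-k = 4 — all regions routed, i.e.
  global attention — at the encoder's small token grid, with 1 head; all
  configurable. Grids not divisible by S are zero-padded internally; pad
  tokens are masked out of the key set and cropped from the output. Top-k
  selection is treated as a constant during backpropagation (its gradient
  is zero almost everywhere).
* **CCA**: 1×1 projections to a reduced Q/K width (C/8 by default, the
  original criss-cross choice), value projection at full width; each
  position attends to the H+W−1 positions of its row and column, softmax
  normalised, and the aggregate is added residually to the input
  (recurrence = 1 by default; recurrence = 2 — the original design's
  choice — propagates information between every pair of positions, which a
  perturbation test demonstrates).

Every layer is implemented in base R with an exact hand-written backward
pass; the test suite checks all of them against central-difference numeric
gradients. Convolutions are evaluated as one BLAS matrix multiply per
kernel tap, which is fast at the feature-map sizes involved. Attention
logits are scaled by 1/√d. Parameters are initialised Kaiming-style from an
explicit integer seed; the same seed rebuilds bit-identical models. A
normalisation choice worth flagging: DeepLab-family networks use batch
norm, whose statistics depend on batch composition and break exact
determinism at batch size 1; we use channelwise layer normalisation after
every convolution instead (plus the two standard layer norms inside the
BiFormer block), which is deterministic, batch-size independent, and in our
experiments necessary for stable SGD at usable learning rates.

## Loss

`cedice_loss = α·CE + (1−α)·(1−Dice)` with α = 0.5 by default (configurable
in `loss_config()`). CE is the mean over pixels of −log p(true class). The
Dice term is soft (computed on probabilities, smoothing ε = 1) and
macro-averaged over foreground classes present in the truth: background is
excluded because the per-structure results of interest are foreground-only,
and absent classes are excluded so that a plane containing five structures
is not averaged against nine vacuous ones. With hard masks and ε→0 the
per-class term reduces exactly to 2|A∩B|/(|A|+|B|).

Cross-entropy can be class-weighted. `train()` by default derives
median-frequency balancing weights from the training masks
(`median_frequency_weights()`: weight = median class frequency / class
frequency, clipped to [0.05, 20]) — the standard remedy for the extreme
background dominance of these images, where unweighted CE drives the model
to the all-background solution long before the rare thin vessels receive
any gradient. Pixel and batch reductions are means.

## Metrics

Per class (one-vs-rest pixel counts): PA = (TP+TN)/N, Dice =
2TP/(2TP+FP+FN), IoU = TP/(TP+FP+FN). A class absent from both masks is
flagged unevaluable rather than producing 0/0. The average surface distance
uses 4-connectivity boundaries (a mask pixel with at least one 4-neighbour
outside the mask; the image border counts as outside), Euclidean distances
between pixel centres, and the symmetric normalisation: the summed
nearest-boundary distances in both directions divided by the total boundary
count. ASD is therefore in pixels and unbounded; we do not replicate any
normalisation of it onto [0, 1]. When the truth contains a class the
prediction misses entirely, the image diagonal is reported as the
worst-case distance rather than dropping the image.

`metric_report()` pools confusion counts over the evaluation set per class
(one number per class, the convention of per-structure results tables) and
averages ASD over the images whose truth contains the class; macro means
(mIoU/mDice/mPA/mASD) are unweighted means over evaluable foreground
classes.

## Data handling

Annotations are Labelme-dialect JSON polygons. Rasterisation uses the
even-odd rule with pixel centres at (integer + 0.5) in 0-based coordinates;
later shapes overwrite earlier ones (the model trains on a single
multi-class map, so instance overlaps are flattened — the annotation tool
speaks "instances", the network "semantics", and last-wins is our explicit
convention). Out-of-bounds vertices are clipped with a warning;
self-intersecting polygons warn and fill even-odd. Masks are stored as
grayscale PNGs whose 8-bit pixel value is the class id, which round-trips
exactly.

Splitting is patient-grouped: whole patients are shuffled under one
explicit seed and assigned, stratified by each patient's primary plane,
targeting per-plane image-count ratios (8:1:1 by default). When exact
ratios and patient independence conflict, patient independence wins and
ratios are approximate; each partition is first seeded with one patient so
no partition is silently empty, and fewer than three patients in a plane is
an error. Cross-validation assigns whole patients to k folds round-robin
(per-plane fold sizes differ by at most one patient).

## The phantom generator

`generate_phantom()` emulates the statistical structure of the seven
standard planes, not ultrasound physics: an elliptical "abdomen" (interior
intensity 0.45, exterior 0.05), per-plane structure subsets (e.g. the
abdominal circumference plane carries UV, IVC, ST, AO, SP; kidney planes
carry lateralised LK/RK), with each structure a polygon primitive — an
anechoic ellipse for stomach/bladder, thin tubes for vessels, bright wedges
for spine/ilium — whose signed contrast against the intra-abdominal
background is exact before degradation. Degradations are a linear depth
attenuation (15 % by default) and multiplicative speckle: Rayleigh noise,
box-smoothed to set the grain, standardised to mean 1 and a configured
coefficient of variation (0.25 by default). Positions and sizes jitter
within bounded ranges around plane templates; the left kidney always stays
left of the midline (and the right kidney right), which is what makes the
flip-augmentation label swap testable. Images default to 128×128 pixels —
large enough that the thinnest tube analogues survive the stride-4 decoder
bottleneck, small enough for CPU-scale training. `generate_dataset()` gives
every synthetic patient a base anatomy per plane and perturbs it by ≤ 2 px
translation and ≤ 5 % scale per image, so patient-grouped splitting has
something real to protect.

What the phantoms do **not** emulate: acoustic shadowing and enhancement,
probe-angle anisotropy, anatomical covariance between structures, inter-
patient size distributions, or any device variability. Tests passing on
phantoms therefore validate the algorithmic contracts (shapes, losses,
metrics, leakage, trainability and the large-vs-small structure ordering),
not clinical segmentation accuracy.

## Training loop

SGD with momentum 0.9 and weight decay 1e-4 (both configurable) on the
compound loss; learning rate follows the per-epoch closed form
lr₀·½(1 + cos(πe/E)) (initial 0.01, 120 epochs by default, matching the
usual schedule for this architecture family), optionally preceded by a
linear warmup (`warmup` epochs, default 0 — the default schedule is the
pure cosine). Augmentation applies the same geometric transform to image
(bilinear) and mask (nearest): horizontal flip with LK/RK label swap
(p = 0.5), rotation within ±15°, scaling 0.8–1.2 — parameter values chosen
as field conventions since only the augmentation families are standard.
The best-validation-mIoU checkpoint is retained. Everything is driven by
one integer seed: two runs with the same seed produce identical losses and
parameters, and validation/test data influence nothing but checkpoint
selection (asserted by a permutation test).

## Problem sizes used in the test suite

The suite exercises genuine training at sizes chosen for a single CPU: the
oracle and property tests run on feature maps ≤ 16×16; the overfit smoke
test trains the tiny profile (widths 8/16/32/32) on 4 phantoms for 200
epochs (batch 1, lr 0.2, 30 warmup epochs, no weight decay, no
augmentation) and requires training soft-Dice > 0.9; the scaled-down
end-to-end experiment trains on 60 ACS phantoms for 30 epochs (batch 4,
lr 0.1, 5 warmup epochs, default augmentation) and asserts only the
qualitative per-structure ordering — the large anechoic stomach analogue
must outscore the thin low-contrast IVC analogue on held-out patients. The
magnitudes of clinical-scale results are out of reach of synthetic data and
CPU budgets by design; the ordering is not.

## Known limitations

* No GPU path and no mini-batch vectorisation: training cost grows
  linearly with images × epochs; the default (non-tiny) profile is
  CPU-expensive and intended for serious runs, not tests.
* Bilinear ×4 decoding bounds boundary sharpness; very thin structures are
  systematically the hardest, as in the clinical problem.
* The BiFormer routing hyperparameters (S, top-k, heads) default to the
  safe global-attention regime at small token grids; speed benefits of
  sparse routing only appear at larger grids.
* Checkpoints are R serialisations (`.rds`); no interchange format.
* `cosine_lr()` with warmup deviates from the pure closed form during the
  warmup epochs by construction; the default configuration has no warmup.
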