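---
title: "Dual-consistency semi-supervised segmentation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-consistency semi-supervised segmentation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcseg)
```

## The problem

Pixel-accurate annotation of histopathology images is expensive: delineating
tumor boundaries on even one slide takes an expert pathologist substantial
time, so labeled patches are scarce while unlabeled patches are abundant.
Semi-supervised segmentation aims to exploit the unlabeled pool. `dcseg`
implements a consistency-regularization approach in which the perturbation
is *architectural* rather than input-space: a single encoder-decoder network
produces several predictions of the same image from different depths of its
decoder, and agreement between those predictions is rewarded on unlabeled
data.

## Model

The backbone is a U-Net: `encoder_depth` (default 4) convolution + max-pool
stages, a bottleneck, and a mirrored decoder with skip connections. Each of
the `S` deepest decoder stages carries a light prediction head -- dropout,
a 1x1 convolution to `K` class channels, bilinear upsampling to the input
size, and a channel softmax -- giving multi-level probability maps
`p_1, ..., p_S`. `p_1` comes from the deepest (coarsest) decoder stage and
`p_S` from the shallowest, full-resolution stage. A multi-scale convolution
module (MSC) additionally fuses the three shallowest decoder feature maps:
a 1x1 convolution compresses their concatenation, parallel poolings at
windows 1, 2, 3 and 5 (stride = window) capture context at several
receptive fields, each pooled branch is bilinearly upsampled back and
concatenated, a 3x3 convolution fuses the result, and a final 1x1
convolution + softmax emits the fine-grained map `p_0`.

Training minimizes

* **supervised**, on labeled images: `L_sup = sum_s alpha_s L(p_s, y)` over
  all available levels (including `p_0` when the MSC is active), where `L`
  is an equal mix of cross-entropy and Dice loss and every `alpha_s = 1`;
* **hierarchical consistency with uncertainty rectification**, on
  unlabeled images: with `p_avg = mean(p_1, ..., p_S)`, each level is pulled
  toward `p_avg` under a per-pixel weight `w = exp(-D)`, where `D` is the
  KL divergence from the level's class distribution to the average's.
  Pixels on which the levels disagree strongly (typically boundaries and
  upsampling artifacts) are down-weighted;
* **coarse-fine grained consistency**, on unlabeled images: the coarse map
  `p_1` is pulled toward the fused fine map `p_0`, which acts as a
  pseudo-label (its gradient is blocked);
* the unsupervised mix `L_unsup = beta * L_urc + (1 - beta) * L_cr`
  (default `beta = 0.5`) enters the total as `L_sup + lambda(t) * L_unsup`
  with the Gaussian warm-up `lambda(t) = k * exp(-5 (1 - t/T)^2)`,
  `k = 0.1`, so consistency pressure grows from `k e^-5` to `k` over the
  run.

The optimizer is SGD with momentum 0.9 and weight decay 1e-4; batches of 20
mix labeled and unlabeled items at 1:4.

## Norm and gradient conventions

The consistency "L2 distances" are implemented as the per-pixel squared
difference **summed over class channels and averaged over pixels** (and
levels / batch items). This convention is pinned by the package's unit
tests; for two classes it differs from a channel-averaged mean square only
by the constant factor `K`.

Three quantities are treated as constants during backpropagation:

* `p_avg` in the rectified term. For the *unweighted* hierarchical term
  this is not an approximation at all -- the gradient contribution through
  `p_avg` cancels exactly because `sum_s (p_s - p_avg) = 0`;
* the uncertainty weights `w` (they modulate, but are not themselves
  optimized);
* `p_0` in the coarse-fine term, per its pseudo-label reading. A
  `detach_p0 = FALSE` switch enables the symmetric variant for ablation
  work.

KL divergences and cross-entropies clamp their logarithm arguments at
1e-8; the Dice loss uses a smoothing constant of 1e-5.

One indexing convention deserves a flag: the framework's own description of
which level is "coarse" is ambiguous (the coarsest map is produced by the
deepest decoder stage but upsampled to full resolution like every other).
`dcseg` takes `p_1` to be the deepest stage's prediction so that the
coarse-fine pair `(p_0, p_1)` spans the largest representational gap; this
is a convention choice, not a claim about the original authors' intent.

## The compute engine

No deep-learning runtime is required: the package carries its own compact
CNN engine (RcppArmadillo). Convolutions are evaluated as nine
pointer-shifted GEMMs over a once-padded feature buffer; bilinear
resampling, pooling and their adjoints are hand-written, and the full
backward pass was validated against central finite differences (relative
error ~1e-6 in double precision) and against independent R-level
re-implementations of every loss term. Training runs in single precision;
all verification paths run in double. Determinism: given a run seed, weight
initialization, batch order and dropout streams are derived at fixed
offsets, and repeated runs reproduce training histories bit for bit on a
single-threaded BLAS.

## What the synthetic generator emulates

`patch_spec()` / `generate_patch()` draw H&E-like patches: an eosin-pink
textured background and one or more "tumor" blobs -- ellipses perturbed by
low-frequency radial harmonics, irregular enough that boundary tracing and
polygon sampling are non-trivial -- with class-specific mean colors
(hematoxylin purple for tumor; in five-class mode blobs cycle over
tumor/stroma/lymphocyte/necrosis), low-frequency luminance mottle, and
per-pixel Gaussian noise (default sd 0.1, a deliberately strong texture
level so that color thresholding alone is not a perfect segmenter).
`generate_wsi()` mosaics the same model into a multi-tile slide stand-in
with blobs spanning tile boundaries.

The generator does **not** model nuclei-level structure, stain variation
between slides, blur/artifact regions, or scanner formats. Passing the
packaged benchmark therefore shows that the training dynamics behave as the
method intends under controlled conditions -- not that any particular
accuracy would be reached on real slides.

## The packaged benchmark

`ssl_benchmark()` is the package's scaled-down counterpart of full-scale
GPU comparisons: one fixed synthetic dataset of 200 training patches
(64 x 64, 2 classes, 20% labeled) and 50 held-out patches; three arms --
supervised-only control, hierarchical-consistency-only (`beta = 1`, no
MSC), and the full dual-consistency method -- each trained for 300
iterations at batch 20 across 5 run seeds with a tiny constant-width
backbone (`base_width = 16`, `growth = 1`). Problem sizes were chosen so
the whole benchmark runs on one CPU core in minutes while still training to
a useful accuracy (held-out Dice well above 0.9). The mirrored expectations
are directional only: mean held-out Dice of the full method at or above the
supervised control, and at or above the HC-only arm.

Two protocol choices worth noting: the supervised control trains on full
batches of 20 labeled items (the standard supervised-baseline protocol --
it sees the same labeled set, more often), and the same fixed dataset is
shared by all arms and seeds so that only initialization, batch order and
dropout vary between runs.

## Slide tooling conventions

* Tiling is 0-based and half-open with fully-inside placement; a
  zero-padding mode is available for edge tiles.
* A pixel counts as background when its minimum RGB channel exceeds 0.85;
  patches with more than 50% background are excluded. A patch is a tumor
  sample only when its tumor-pixel fraction strictly exceeds 25%.
* Overlapping stitched predictions are averaged in probability space
  before the argmax (last-write-wins is available).
* Contours are traced on 8-connected components with Moore-neighbor
  tracing; every 15th boundary pixel along the traced chain is kept (the
  first always), components yielding fewer than 3 vertices are dropped,
  and coordinates are multiplied by the magnification factor (working
  resolution to slide space, e.g. 4 for 40x slides processed at 10x).
  Whether "15-pixel intervals" is measured along the chain or in every
  15th boundary pixel is equivalent for 8-connected chains up to rounding;
  the chain convention is fixed here and pinned by tests.
* Annotation XML uses the ASAP dialect (`ASAP_Annotations` /
  `Annotations` / `Annotation[Name, Type="Polygon", PartOfGroup, Color]` /
  `Coordinates` / `Coordinate[Order, X, Y]` plus an `AnnotationGroups`
  section); coordinates are serialized as exact decimals so write/read
  round-trips are lossless.

## Numerical and degenerate-input choices

* Softmax is computed with max-subtraction; probability maps are
  normalized within 1e-5 at every level.
* Metrics follow one-vs-rest per-class counting; when a class is empty in
  both prediction and ground truth all its metrics are defined as 1, so
  all-background patches do not poison averages; otherwise 0/0 ratios
  resolve to 0. Macro summaries exclude the background class.
* `lambda_schedule()` clamps iterations beyond `T` to the ceiling `k`.
* Max-pool gradients go to the first maximum in scan order on ties.
* Empty annotation documents serialize to valid XML with zero polygons.

## Known limitations

* CPU-only and deliberately small: the engine targets patch sizes of a few
  hundred pixels and widths of tens of channels, not GPU-scale training.
* The supervised arm of the benchmark is close to saturation on the
  synthetic task, so the semi-supervised margin is small (fractions of a
  Dice point); the benchmark checks direction, not magnitude.
* No stain normalization, augmentation beyond optional flips, or
  mean-teacher weight averaging -- the method's perturbation is the
  multi-level architecture itself.
* Proprietary slide formats (MRXS, NDPI) are out of scope; the slide
  tooling operates on in-memory arrays / TIFF stand-ins.
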