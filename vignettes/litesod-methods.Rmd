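---
title: "liteSOD: model, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{liteSOD: model, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`liteSOD` implements a lightweight salient-object-detection network for
locating bone regions in livestock X-ray images, together with the saliency
evaluation metrics, a CPU training loop and synthetic data generators. This
vignette records the model as implemented, the parameters that matter, and
the design decisions taken where the architecture description leaves the
construction open.

## The compute engine

No deep-learning framework is used: the package carries its own dense
tensor engine. Activations are column-major `(H, W, C, N)` arrays;
convolutions run as im2col + BLAS matrix products in compiled code, with
analytic reverse-mode gradients for every operation (convolution, batch
normalization, bilinear resampling, max/adaptive-average pooling, the
attention products and the softmax over branches) assembled on a dynamic
tape. Gradients are verified against central differences, and every forward
block is checked against straight-line loop implementations in the tests.
Determinism is exact: all initialization and training randomness flows from
configuration seeds through R's RNG.

## Encoder

Five stages with stride-2 entry convolutions; widths 16, 32, 64, 96, 128,
so a 224×224 input passes 112 → 56 → 28 → 14 → 7 and ends at 7×7×128.
Channel growth is deliberately limited — width is capped at 128 rather than
doubling per stage — which is where most of the parameter saving against
VGG/ResNet-backbone saliency models comes from.

Each stage ends in a multiscale attention module (MAM):

* a shared 3×3 conv–BN–ReLU;
* three dilated 3×3 branches at 2×, 1× and 0.5× spatial scale (dilations
  1, 2, 4). The construction of the scale branches is a design choice: the
  2× branch is bilinear-upsample-then-convolve, the 0.5× branch is
  average-pool-then-convolve, and both are resized back bilinearly
  (`align_corners = FALSE` convention) before the element-wise sum;
* per-branch attention gates: each branch owns a channel-attention head
  (global average pool → two-layer 1×1 bottleneck, reduction 4 → sigmoid)
  and a spatial-attention head (per-pixel channel mean+max → 3×3 conv →
  sigmoid). The gate logit of branch *i* is the outer product of its channel
  and spatial weights, and the three gates are normalized with a softmax
  **across branches**, per pixel and channel. This axis is the only reading
  under which the attention selects among scales; a single shared gate would
  make the softmax collapse to 1/3 everywhere;
* a 1×1 fuse convolution and a residual addition of the module input.
  Zeroing every MAM parameter therefore reduces the module exactly to the
  identity, which the tests assert bitwise.

One construction detail: the half-scale branch uses ceiling division when
halving, so the terminal 7×7 stage is well defined inside the network. The
exported `mamForward()` keeps the strict even-size contract and rejects odd
inputs.

The parameter budget is tuned with `blocksPerStage`: widths and the
refinement schedule are fixed, and the default block schedule
`c(1, 1, 1, 3, 3)` places the extra 3×3 blocks in the two deepest stages
(where they are cheap in compute but parameter-dense), bringing the
assembled network to 2 101 699 trainable scalars — 2.1 M at one decimal.

## Decoder

The terminal feature is pyramid-pooled (bins 1, 2, 3, 6 — the standard
pyramid-pooling configuration; the bins are configurable) into a
global-context feature `P`. Four decoder stages then mirror encoder stages
4..1 in resolution (14, 28, 56, 112) and width (96, 64, 32, 16).

Each stage concatenates four sources — encoder maps at the same or finer
scale and decoder maps / `P` at coarser scale, per the fixed wiring table
(`scmWiring()`) — after reducing each source to exactly 1/4 of the stage
width (floor, minimum 1) and resizing it to the stage resolution. The
concatenated map passes a 3×3 conv–BN–ReLU and is added element-wise to the
carried feature (`P` for stage 4, the previous decoder stage otherwise),
itself resized and 1×1-projected (`resizeAdjust`). Two points here are
design choices rather than prescriptions: the carried feature must be
resized for the addition to be defined, and a single 3×3 convolution
follows the concatenation. The quarter-width reduction is asserted exactly
in the tests (`4 × quarter = stage width`), as is the full-scale coverage
property: every encoder stage feeds at least one decoder stage and `P`
feeds all four.

A 3×3 head on the finest stage, bilinear 2× upsampling and a sigmoid
produce the coarse 224×224 saliency map.

## Refinement

The refinement module is a symmetric encoder–decoder over the coarse map
alone (no image concatenation): five one-convolution stages with 3×3
filters 4, 8, 16, 24, 36, 2×2 max pooling between encoder stages, bilinear
2× upsampling between decoder stages whose filters mirror the schedule
(36, 24, 16, 8, 4), and a final 3×3 single-channel output. Whether the
printed schedule covers the decoder as well is ambiguous; mirroring is the
minimal symmetric reading and is what the parameter accounting assumes.

The residual is added in **logit space**: the refined map is
`sigmoid(head_logits + residual)`. Adding probabilities directly could
leave [0, 1]; the logit form keeps the output bounded and makes the
degenerate case exact — a zeroed refinement module returns the coarse map
bit for bit.

## Metrics

* `saliencyMAE`: mean absolute pixel difference.
* `maxFMeasure`: F = (1+β²)PR/(β²P+R) maximized over 256 evenly spaced
  binarization thresholds with strict `>` (an adaptive-threshold variant
  sits behind a flag). β² defaults to 0.3, the convention shared by the
  methods this family of models is compared against; the alternative 0.03
  sometimes printed in this context is reachable through `metricConfig()`.
  The strict inequality makes the inverted-prediction case score exactly 0
  at every threshold, and the sweep is invariant under strictly monotone
  rescaling of the prediction.
* `weightedFbeta`: the dependency-aware variant. The error map |p − y| is
  propagated outward (each background pixel adopts the error of its nearest
  foreground pixel, found by an exact Euclidean distance transform),
  smoothed with a 7×7 Gaussian (σ = 5) inside the foreground where
  smoothing helps, and background errors are weighted by
  2 − exp(ln(0.5)/5 · d). β² = 1, and the constants are exposed in
  `metricConfig()`. The implementation uses a Felzenszwalb–Huttenlocher
  transform with nearest-index tracking; the tests pin it to a dense
  brute-force implementation on small fixtures.
* Masks load as binary via a ≥128/255 threshold (benchmark masks are often
  anti-aliased); predictions are 8-bit grayscale PNGs, so file-based and
  in-memory evaluation agree to 1/255 quantization.

## Training

Adam (β₁ = 0.9, β₂ = 0.999, no weight decay) with initial learning rate
3e-4 and per-epoch cosine annealing to zero; 60 epochs and random
horizontal flipping (probability 1/2, image and mask mirrored together) are
the defaults. The loss is plain binary cross-entropy on both the coarse and
the refined map with equal weights — the supervision loss is the package's
own choice, applied in logit form inside the loop for numerical stability
(the exported `bceLoss` operates on probabilities with an ε-clip). Batch
size defaults to 16.

A practical note on batch normalization: training-mode forwards use batch
statistics while inference uses running averages (momentum 0.1). After very
short runs (tens of steps) the two can disagree noticeably; the training
log's `trainMAE` column tracks the training-mode maps, and evaluation-mode
quality catches up as the running statistics converge (on the order of a
hundred steps).

## Synthetic data

Two seeded regimes, written as `images/NNN.png` + `masks/NNN.png` +
`manifest.json` and byte-identical under regeneration:

* **blob** — 1–3 smooth wobbly ellipses (possibly crossing the border) on a
  textured background; mask = union of the shapes, with foreground fraction
  kept in [0.02, 0.6]. Defaults: contrast 0.6, pixel noise 0.05. At full
  contrast and zero noise the scene is clean enough that Otsu thresholding
  recovers ≥99% of the mask — the generator's self-consistency check.
* **xray** — a dark field, a brighter soft-tissue region bounded by a
  random smooth closed contour, and inside it an elongated curved bone
  ridge (quadratic spline tube, branched at one end with probability 1/2),
  brighter than the tissue by the configured contrast. Defaults: contrast
  0.15 and noise 0.03 — noise below half the contrast, so the bone stays
  statistically detectable but visually faint, which is the difficulty
  regime of interest. The mask is exactly the bone tube and is constructed
  strictly inside the tissue. Typical bone fractions run 3–10% of pixels.

What these generators emulate is the geometry and contrast statistics of
the task — small low-contrast elongated targets in clutter — not the image
formation: there is no beam hardening, scatter, anatomy or annotation
noise. Tests passing on synthetic data therefore demonstrate that the
architecture, gradients, metrics and training loop are correct and that the
model class can represent and learn such targets; they do not certify
performance on real radiographs.

## Problem sizes and numerical choices

The test suite keeps everything desk-scale: oracle comparisons use tensors
up to 6×6, statistical envelopes use 120–150 generator draws, and the
learnability check overfits 16 synthetic scenes with batch 4 for at most
200 optimizer steps (it typically stops after a few epochs once the
training MAE is below 0.04). Batch-norm ε is 1e-5; Adam ε 1e-8; BCE clip
1e-7; weight initialization is Kaiming-uniform with batch-norm γ = 1,
β = 0, all under the configuration seed.

## Known limitations

* Training is single-threaded CPU; a full 60-epoch benchmark-scale run is
  out of reach by design — the loop exists to make the recipe executable
  and testable at small scale.
* Batch-norm running statistics lag batch statistics on very short runs
  (see above).
* The checkpoint format is R serialization (RDS) and is not interoperable
  with other frameworks.
* The synthetic X-ray regime is a statistical stand-in; no claim is made
  about real pig-leg radiographs.
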