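---
title: "Methods: coral segmentation from single-channel images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coral segmentation from single-channel images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Coral monitoring surveys produce large volumes of underwater imagery — RGB
photographs and single-band spectral frames — from which ecologists want the
coral *coverage*: the fraction of pixels occupied by coral. coralseg assigns
every pixel of a single-channel grayscale image to one of two classes, coral
or background, using a convolutional encoder–decoder, and reports the
standard segmentation metrics (precision, recall, F1, mean IoU). Working on
one channel at a time keeps RGB photographs and single-band spectral frames
in the same representation: an RGB photo is split into its R, G and B planes
and each plane is segmented as an independent grayscale image.

## The network

The model is a compact encoder–decoder:

* **Backbone.** A ResNet34 feature extractor pruned of its final residual
  stage. The stem (7×7 stride-2 convolution, batch normalization, ReLU, 3×3
  stride-2 max pooling) produces *low-level* features at output stride 4.
  Three residual stages of basic blocks (`y = F(x) + x`, two 3×3
  convolutions per block) with block counts 3/4/6 follow — 26 convolutions
  in the residual stages — with stages 2 and 3 halving resolution, so the
  *high-level* output sits at stride 16 with 256 channels at full width.
  Shortcut projections (1×1, stride-matched) carry the identity when a block
  changes shape; they are not counted in the 26.
* **ASPP.** Atrous spatial pyramid pooling over the high-level features:
  four parallel dilated 3×3 convolutions (the rate-1 branch degenerates to a
  1×1) plus a global-average-pooling branch broadcast back over the grid,
  concatenated and reduced to 256 channels by a 1×1 convolution. The
  dilation rates default to {1, 6, 12, 18}, the DeepLab-family convention;
  they are configurable because no single set is canonical.
* **Low-level path.** The stride-4 stem features are reduced by a 1×1
  convolution (64→32 channels at full width) and brought to stride 16 by
  space-to-depth with block factor 4 — a lossless rearrangement `(C, H, W) →
  (C·r², H/r, W/r)` that trades resolution for depth without discarding
  texture information. Its inverse, depth-to-space, is used in the decoder.
  Both use one fixed convention (row-major within each r×r block, blocks
  filling channels fastest) so they are exact mutual inverses.
* **Decoder.** Low- and high-level features are concatenated on channels and
  fused by two large-kernel (7×7) convolutions at 256 channels — the large
  kernel buys receptive field at the fused stage — then a 1×1 prediction
  convolution to `2·16` channels, depth-to-space back to stride 4, and
  bilinear ×4 interpolation to full resolution, yielding 2×S×S class scores.
  The predicted mask is the per-pixel argmax, ties to background.

All widths scale with a single `width_multiplier`. The architecture is
size-agnostic for input sides divisible by 16; full-scale work uses 512-pixel
inputs and `width_multiplier = 1`, desk-scale experiments 64-pixel inputs and
`width_multiplier = 0.25`. The numerical core (convolution with stride,
padding and dilation, batch normalization, pooling, bilinear resampling, and
all their gradients) is implemented in C++ (Rcpp/RcppArmadillo) and
backpropagation and Adam are implemented directly in the package, so training
runs anywhere R does, with no deep-learning framework dependency. Gradient
correctness is pinned by finite-difference tests.

## Training procedure

Two phases, both with Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8, the standard
defaults) and an exponentially decayed learning rate
`v(j) = α^j · v0` applied per epoch with `j` starting at 0, so epoch 0 uses
`v0` exactly. Reference-scale defaults are `v0 = 1e-4`, `α = 0.99`,
200 epochs at batch 32 for pre-training and 150 epochs at batch 16 for
segmentation.

1. **Backbone pre-training** attaches global average pooling and a 2-class
   linear head to the backbone and trains on image-level labels
   (coral present / absent).
2. **Segmentation training** initializes the encoder from phase 1 and
   minimizes the pixel-wise cross entropy `H(ygt, yp) = −Σ ygt · log yp`
   (softmax over the two channels, log-sum-exp stabilized). The sum is
   averaged over pixels and batch so the loss is comparable across image
   sizes; `reduction = "sum"` gives the unnormalized form.

Training images are augmented with three independent coin-flips (probability
0.5 each): rotation by an angle uniform on [0°, 180°] (continuous — no
discretization is implied), horizontal flip, vertical flip. The identical
geometric transform is applied to image and mask; images are resampled
bilinearly, masks by nearest neighbor so they stay binary; rotation is
counter-clockwise about the center with black fill. The draw order (rotate?,
angle, hflip?, vflip?) is fixed and the angle is drawn even when rotation
does not fire, so a seeded run is exactly replayable. Validation images are
never augmented. Batches are reshuffled each epoch with the run seed and the
last partial batch is kept. No early stopping, weight decay or class
weighting is used.

**Precise batch-norm refresh.** After each epoch the package recomputes every
batch-normalization layer's running statistics in a single momentum-1 pass
over the unaugmented training set. With the conventional momentum-0.1 running
average, short desk-scale runs (tens of optimizer steps) evaluate with badly
uncalibrated moments; the refresh makes evaluation-mode forward passes
consistent with the training distribution at any run length, and makes
per-epoch validation curves meaningful from epoch 0.

## Metrics

Per image: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean
F1, and mean IoU. Mean IoU averages the per-class IoU
`TP_k/(TP_k+FP_k+FN_k)` over the *two* actual classes (background, coral) —
the PASCAL-VOC-style convention of counting foreground classes plus
background, which is the only normalization consistent with binary output. A class absent from both masks is skipped (its IoU is undefined, not
perfect), and degenerate precision/recall denominators yield an explicit
`NA` that is excluded from dataset aggregates — silently scoring an empty
prediction on a negative image as 0 or 1 would distort means. Dataset-level
aggregation is macro (mean ± population standard deviation over per-image
values, divisor N); a pixel-pooled micro variant is also reported because the
macro/micro choice is a genuine convention fork.

## Class activation mapping

For weak localization from image-level labels only, a CAM head taps the
fused 256-channel decoder features (the semantically richest full-depth map;
the tap point is configurable in principle). A 1×1 convolution produces two
response maps N0 (non-coral) and N1 (coral); global average pooling gives
their means G0, G1; scalar weights form a coral evidence score
`s = w0·G0 + w1·G1 + b`, trained with sigmoid cross entropy on the
image-level labels while the trunk stays frozen. The activation map is
`CAM = w0·N0 + w1·N1`, normalized to `(CAM − min)/(max − min) × 100` percent
(a constant map maps to zeros by convention). Because averaging commutes
with the weighted sum, the map is exactly the spatial decomposition of the
score: `mean(CAM) = s − b`. This is the property that makes red mean coral —
a per-class diagonal scoring (`logit_j = w_j·G_j`) leaves the sign structure
of the two maps underdetermined and in our experiments localized background
as often as coral, so the single-score form is the one the package trains.
Min-max normalization is invariant to positive affine transforms of the raw
map, so the rendered heat map does not depend on the score's scale.

## Synthetic scenes

The generator emulates the *structure* of an annotated coral survey at desk
scale: single-channel scenes with paired pixel masks and image-level labels,
interchangeable with real data through the same manifest schema. A positive
scene (probability 0.65 by default, the empirical positive share of the
reference collection, 2672/4131) contains a union of 1–4 random ellipses —
a crude massive/branching coral silhouette — with sinusoidal texture
(amplitude 0.05) and intensity offset +0.4 over a 0.25 background;
everything is corrupted by Gaussian noise (sd 0.1) and optionally a vertical
illumination ramp mimicking unevenly lit single-band frames. The
offset-to-noise ratio (~4, gated by `foreground_separability()`) keeps the
classes separable so short CPU runs can succeed. The generator is a pure
function of its configuration and seed; a JSON descriptor reproduces a
dataset byte-for-byte.

What it does *not* emulate: water optics, color casts, species morphology,
occlusion, annotation noise, class imbalance at the pixel level beyond blob
geometry. Passing desk-scale tests therefore demonstrates that the
architecture, losses, gradients and training loop work — not that the model
generalizes to real reef imagery; that requires the real annotated data and
full-scale training.

## Desk-scale problem sizes

The test suite and the acceptance pipeline use: 64-pixel scenes and a
quarter-width model throughout; an overfit regime of 8 positive scenes
memorized for 200 steps at `v0 = 2e-3` (batch 8, no augmentation); and an
end-to-end pipeline of 80 scenes (64 train / 16 validation), 4 pre-training
epochs at batch 16, 16 segmentation epochs at batch 8 (`v0 = 1e-3`), and 10
CAM epochs at `1e-2`. The desk learning rates are higher than the
reference-scale `1e-4` because tiny networks on separable data tolerate —
and short runs need — larger steps. These sizes were chosen once as the
package's standard desk experiment; across seeds they give held-out mean IoU
in the 0.84–0.93 range and overfit training mean IoU above 0.95.

## Numerical conventions and edge cases

* Pixels are row-major with the origin at the top-left; coordinates are
  0-based in the C++ kernels and 1-based in R matrices.
* Images load as doubles in [0, 1]; 8-bit PNG round-trips are exact to
  1/255. Masks binarize at 0.5 (>127 of 255), absorbing anti-aliasing.
* Padding to 1:1 aspect ratio is centered on both axes and black (zero),
  generalizing the top/bottom bands of landscape spectral frames to either
  orientation; the clipping rule of the original preprocessing is not
  specified, so the package pads-then-scales only.
* Resampling uses half-pixel sample centers; bilinear for intensities,
  nearest-neighbor for masks.
* Weight init is He fan-in-scaled normal, seeded; a `zero_init_residual`
  switch zeroes each block's last BN scale so `F(x) = 0` exactly (used to
  test the residual identity).
* Batch normalization uses ε = 1e-5; a batch whose channel variance is zero
  normalizes to the β offset rather than dividing by zero.
* Ties in the argmax decision go to background; constant activation maps
  normalize to zero.
* Undefined metric values are `NA`, never silently 0 or 1.

## Limitations

Single-threaded CPU training bounds practical problem sizes; full-scale
(512-pixel, full-width, thousands of images) training is expressible but
slow in this implementation. Only binary segmentation is supported, matching
the coral/background task. The model-plugin surface is the ordinary function
boundary (`build_model`/`deeperlabc_forward`): alternative architectures can
be evaluated with the same metrics and CLI but no registry is provided.
JPEG reading requires the optional `jpeg` package.
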