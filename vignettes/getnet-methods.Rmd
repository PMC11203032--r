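---
title: "Methods: a volumetric windowed-attention U-Net with channel attention and group-normalization shuffle blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a volumetric windowed-attention U-Net with channel attention and group-normalization shuffle blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(getnet)
```

## The problem and the model

Gliomas are evaluated on multi-modal MRI (T1, T2, T1ce, FLAIR) against three
*nested* regions: whole tumor (WT), tumor core (TC) and enhancing tumor (ET),
with WT ⊇ TC ⊇ ET. Convolutional U-Nets capture local texture but have
limited receptive fields; pure transformer U-Nets capture long-range
dependencies but under-use local detail. GETNet addresses this by inserting
two convolutional components into a volumetric windowed-attention U-Net:

* a **GNS block** (group-normalization shuffle) after every encoder
  attention stage, before downsampling — a two-branch
  split/transform/concat/shuffle unit in the ShuffleNetV2 style whose
  transform branch is `1×1×1 conv → GN+GeLU → 3×3×3 depth-wise conv → GN →
  1×1×1 conv → GN+GeLU` (layout "E", the best of the five unit layouts in the
  original ablation; layout "A", the batch-norm/ReLU original, is kept behind
  `gns_layout` for structural comparison);
* an **ECSA block** (enhanced channel self-attention), used twice in the
  bottleneck inside a pre-norm transformer wrapper
  `y = ECSA(LN(x)) + x; Z = y + MLP(LN(y))`. ECSA gates the channels of a
  query, key and value path with squeeze-style sigmoid gates
  (`sigmoid(FL(ReLU(FL(AP(x)))))`), forms the Hadamard product of the gated
  query and key features, passes it through a 7×7×7 depth-wise convolution
  (local context at a large receptive field) and a 1×1×1 aggregation
  convolution, normalizes with a softmax and gates the value path with the
  result.

The surrounding U-Net follows the volumetric-transformer design: patch
partition and linear embedding; per stage, one window-attention (W-MSA) block
and one shifted-window (SW-MSA) block; depth-halving patch merging
(`(C, D, H, W) → (2C, D/2, H/2, W/2)`); a decoder whose blocks run
self-attention in parallel with cross-attention against the *encoder's*
per-head keys and values, bridged stage-to-stage (the "skip connections" of
this architecture carry K/V, not features); patch expanding back up; and a
final 1×1×1 classifier emitting three overlapping region channels trained
against the binary WT/TC/ET masks with sigmoid activation.

Decoder fusion is the convex combination
`(1 − λ)·CA + λ·SA` with λ = 0.5 (the ablation optimum), followed by an
additive sinusoidal Fourier positional encoding with frequency coefficient
10,000 (also the ablation optimum), the residual into the block input, and a
pre-norm MLP.

## Interpretation decisions

Several published formulas are ambiguous in print; the readings adopted here
are fixed, documented, and in two cases configurable:

* The transformer wrapper formula is bracket-ambiguous; it is parsed as the
  conventional pre-norm residual pair (see above).
* The softmax inside ECSA does not state its axis; it is taken over the
  **channel** axis at every voxel, consistent with the block being *channel*
  attention and with the result gating the value path channel-wise
  (configurable in principle through the block's internals).
* The two gate formulas (for the W and SW paths) are printed identically;
  they are implemented as structurally identical gates with independent
  parameters, the value gate acting on raw `x`, the query/key gates on
  `FL(x)`. Whether the `FL` maps of the query/key paths share parameters
  with the output linear is unstated; all are independent here.
* The shifted-window offset is half the window per axis (the Swin
  convention); a learned 3D relative-position bias is included behind
  `relative_bias` since the lineage uses one but the text is silent.
* Whether the GNS output is added residually or replaces the stage features
  is unstated; it replaces them, as the sequential pipeline diagram shows.
* The bottleneck order is ECSA layers first, then patch expanding.
* BraTS label codes are the 2021 convention: WT = {1, 2, 4}, TC = {1, 4},
  ET = {4}; necrotic core 1, edema 2, enhancing 4.

## Preprocessing and augmentation

Cases are processed in the order *read → clip+Z-score → crop → augment*:

* intensities are clipped per channel to the 1st/99th percentiles of the
  nonzero-voxel distribution (linear-interpolation percentiles), then
  standardized to zero mean and unit variance over the nonzero voxels;
  background zeros are preserved exactly. A second application of this
  operator is *not* exactly the identity: interpolated percentiles re-clip
  the tied tails by about one order-statistic gap (~1e−3 at 10⁴ voxels);
  the tests assert near-idempotence at that scale.
* the crop window is drawn uniformly among windows containing the brain
  bounding box (zero-padding when the input is smaller than the patch);
* augmentation applies, each with probability `p_apply` (default 0.5,
  exposed since the source does not state it): rotation by U(−30°, 30°)
  about a random orthogonal plane (labels nearest-neighbour), additive
  Gaussian noise of SD 0.1, Gaussian blur with σ ~ U(0.5, 1) (edge-clamped
  separable kernels), and a gamma transform with exponent U(0.7, 1.5)
  applied on the per-channel intensity range.

## Training, autodiff and numerical choices

No deep-learning framework is available to R in this environment, so the
package carries a small reverse-mode autodiff tape (`R/autodiff.R`) over
dense arrays: linear maps, layer/group normalization, GeLU/ReLU/sigmoid,
softmax, depth-wise convolution (zero padding `(k−1)/2`), window/cyclic-shift
rearrangements and batched scaled-dot-product attention, each with an
analytic backward rule verified against central finite differences.
Training is plain Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8) at the published
learning rate 1e−4 and batch size 1, minimizing soft Dice loss
`1 − mean_r (2Σpt + ε)/(Σp + Σt + ε)` with ε = 1e−5 over the three region
channels.

Initialization is variance-preserving (Glorot) Gaussian for all linear and
convolution weights — at the toy widths used here the common fixed-SD 0.02
transformer init collapses activations and stalls optimization — with unit
normalization gains, zero biases and zero bias tables.

Other numerical conventions: layer/group normalization use population
variance with ε = 1e−5; the GN group count defaults to the largest divisor
of the branch width not exceeding 8 (so tiny test configurations always
divide); GNS layout "A" realizes batch normalization at batch size one as
per-channel statistics; Dice of two empty masks is 1; sensitivity is
undefined (NA) for an empty truth; HD95 uses 6-connectivity boundary voxels,
linear-interpolation percentiles, symmetrization by the maximum of the two
directed 95th percentiles, millimetre spacing (default 1 mm isotropic — on
BraTS grids the two conventions coincide), and returns NA with an `empty`
flag when either boundary set is empty.

The analytic MAC counter charges one multiply-accumulate per scalar
multiply-add in linear, convolution and attention score/apply terms and
ignores normalizations, activations and elementwise gates; since the
baseline's hyper-parameters are not published, only *orderings* of totals
are asserted (depth-halving merging strictly undercuts fixed-depth merging),
never absolute totals.

## The phantom generator: what it does and does not emulate

`generate_phantom()` builds a BraTS-like case on a D×H×W grid: an
ellipsoidal brain of nonzero intensity on an exactly-zero background
(so nonzero-voxel normalization is meaningful), carrying three nested
axis-aligned ellipsoids for WT ⊇ TC ⊇ ET. Intensities are piecewise-constant
tissue means per modality plus Gaussian noise (SD 0.1 in units where tissue
means are of order 1), with edema brightest in FLAIR and the enhancing
region brightest in T1ce, mirroring real contrast orderings. Default
geometry on the 32³ grid: WT semi-axes (9, 8, 8), TC (6, 5, 5), ET (3, 3, 3)
voxels — proportionally a mid-sized lesion. Identical spec and seed give
bit-identical phantoms.

The phantom deliberately omits MRI physics (bias fields, partial volume,
anisotropic spacing), multi-focal lesions and anatomical texture. Passing
tests on phantoms therefore demonstrates that the implementation is
*correct and trainable*, not that it reaches published accuracy on real
data.

## Problem sizes and the toy profile

All tests and the acceptance script run one CPU at desk scale. The shipped
`toy_config()` uses 32³ inputs, 4³ patches, embedding width 8, two encoder
stages with heads (2, 4), window 2³, and the full-scale structural defaults
(λ = 0.5, FPE 10,000, GNS layout E, depth-halving merging, two ECSA layers).
Unit tests exercise blocks at ≤ 3³ spatial and ≤ 4 channels against
loop-based oracles; the end-to-end demonstration trains the toy profile on
one phantom for 200–600 Adam steps.

## Known limitations

* At the published learning rate (1e−4) and batch size 1, a 200-step budget
  moves each parameter by at most ≈ 2e−2, which bounds how far the logits
  can travel from initialization; single-phantom overfitting therefore
  needs several hundred steps before thresholded Dice is high, and the
  tiny ET ellipsoid (~10² voxels) dominates the residual soft-Dice loss at
  4³-patch output granularity. This is a property of the optimization
  recipe at toy scale, not of the architecture: a per-voxel linear
  classifier under the same recipe fits far more slowly than the network.
* Published leaderboard metrics require the full BraTS2021 corpus, GPU-scale
  training and the hidden validation server, and are out of scope; the
  package reproduces the method, its structural ablation directions and its
  metric definitions, not those scores.
* The pure-R autodiff engine favours clarity over speed; it is sized for
  the toy profile (forward ≈ 0.15 s, a training step ≈ 0.25 s) and would
  need compiled kernels for 128³ work.
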