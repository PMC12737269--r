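---
title: "Adaptive discriminator augmentation for volumes: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive discriminator augmentation for volumes: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ada3d)
```

## Scope

`ada3d` implements the data-side machinery of adaptive discriminator
augmentation (ADA) for volumetric images: the volume data model, the
stochastic augmentation pipeline and its probability controller, the
reference semantics of the two common GAN regularizers, and the
evaluation metrics used to compare generated volumes with real ones.
It deliberately contains no neural networks; anything that would
normally be a network enters through a small functional contract
(a value function plus its gradient or vector-Jacobian product), so
every quantity in the package can be verified against closed forms
and brute-force oracles.

## Volume model

A `VolumeGrid` wraps a depth x height x width (`D x H x W`) numeric
array with an intensity-range tag and per-axis voxel spacing. Two
ranges exist:

* `uint8` — integers in `[0, 255]`, the storage/interchange range;
* `model` — the training range obtained by `x / 127.5 - 1`; values
  may exceed `[-1, 1]` after brightness or noise augmentation, which
  is intentional (augmentation must not silently clip).

The width axis is treated as the sagittal (left-right) axis; the
axial plane is `(H, W)`; "middle slices" take the plane at zero-based
index `floor(n/2)` along each axis. NPZ I/O is implemented directly
(NPY v1.0 headers, C-order via axis reversal, deflate with a fixed
timestamp so reruns are byte-identical); NIfTI goes through `RNifti`.
`resampleChain` applies successive trilinear resamplings with
align-corners-off conventions (voxel centres at `(2i - n - 1)/n` in
the normalized `[-1, 1]` cube), matching the default behaviour of the
major deep-learning frameworks, so a preprocessing chain such as
28^3 -> 64^3 -> 32^3 reproduces their pixel grids.

`balanceRoster` down-samples the majority class without replacement
to the minority count; with the default 863/295 composition this
keeps 295 per class (590 total) and removes 568 entries.

## Augmentation pipeline

`augmentBatch` applies five transform categories in a fixed order —
pixel-level, geometric, colour, frequency filter, corruption — each
individual transform gated by an independent Bernoulli draw with the
shared probability `p`. With `p = 0` the pipeline is an exact
identity (tested voxel-for-voxel); with `p = 1` every enabled
transform fires.

**Pixel-level** transforms are index permutations and therefore
lossless: sagittal flip, axial quarter-turns, and integer
translations with reflection padding.

**Geometric** transforms compose homogeneous 4x4 matrices in the
order flip -> axial 90-degree rotation -> integer translation ->
isotropic scale -> arbitrary rotation -> anisotropic scale ->
fractional translation, then apply the inverse warp once with
trilinear interpolation and reflection (half-sample symmetric)
padding. Sampling distributions follow the ADA lineage: lognormal
scales (log-std 0.2 isotropic), rotations from uniform unit
quaternions, fractional translations `N(0, 0.125)` of the extent.
Matrix entries within `1e-9` of integers are snapped, so a composite
that happens to be a lattice motion is executed exactly; this is what
makes the involution tests (`flip^2`, four quarter-turns, `+t` then
`-t`) bit-exact rather than approximately true.

**Colour** transforms are defined on an RGB lift of the grayscale
volume: brightness (additive, std 0.2), contrast (lognormal, log-std
0.5), luma flip (Householder reflection about the luma axis
`(1,1,1)/sqrt(3)`), hue rotation and saturation scaling about the
same axis. Because a grayscale voxel lifts to a point on the luma
axis, hue and saturation are exact no-ops, and the composite 4x4
colour matrix always projects back to a scalar affine map `a*x + b`;
the implementation applies that projection directly.

**Frequency filtering** multiplies four dyadic bands by lognormal
gains (log-std 1). The bands come from a 3-level separable
periodized Haar transform: Haar is the only compactly supported
symmetric orthogonal wavelet, so analysis/synthesis is an exact
inverse pair (round-trip error at machine precision, verified to
`1e-13`) and unit gains reconstruct the input. Volumes must be
divisible by 8 along each axis.

**Corruption** is cutout (a box of half the extent per axis, centred
uniformly, clipped at borders, set to mid-gray) and additive Gaussian
noise with half-normal std (scale 0.1).

Every sampled transform set is recorded as an `AugDraw` (geometry
matrix, colour matrix, band gains, cutout centre, noise std) and
attached to the output, so a run manifest fully determines the
augmentation applied to each volume.

## Controller and schedule

`adaState` tracks an exponential moving average (`lambda = 16/4000`)
of the overfitting statistic `r` = fraction of real-batch
discriminator logits that are positive (zeros count as negative; a
signed-mean convention is also available). After each batch of `n`
images, `p` moves by `n / (speed * 1000)` toward satisfying
`r = target`, clipped to `[0, 1]`, with `target = 0.7` and
`speed = 500` kimg by default — i.e. `p` can traverse the unit
interval in 500k images at constant drive.

`trainSchedule` fixes batch size 16, 300 kimg total (300,000 images,
18,750 batches) and 4000-image ticks (75 boundaries). With the
stylized response model `r(p) = 1 - p`, the closed-loop fixed point
is at `1 - p = 0.7`, and simulation (`runController`) settles with a
trailing-half mean of `p` within a few thousandths of 0.3.

## Regularizer contracts

`r1Penalty(d, reals, gamma)` computes
`(gamma/2) * mean_batch sum (dD/dx)^2` given a discriminator contract
`list(f, grad)`. For a linear discriminator with unit weights on a
`4^3` volume and `gamma = 0.6` this is exactly
`0.3 * 64 = 19.2`; the gradient contract is validated against central
finite differences on a quadratic toy.

`pathLengthPenalty(g, latents, plMean, extent)` projects the
generator output onto Gaussian noise scaled by `1 / sqrt(D*H*W)` and
measures the latent-gradient norm through a vector-Jacobian-product
contract `list(f, vjp)`. The scaling makes expected path lengths
invariant to resolution for generators with resolution-independent
per-voxel statistics; the running mean uses EMA decay 0.01.

## Metrics

**3D SSIM** (`ssim3d`) uses an `11^3` Gaussian window (sigma 1.5),
`L = 1`, `k1 = 0.01`, `k2 = 0.03` (so `C1 = 1e-4`, `C2 = 9e-4`),
valid-region separable convolution, and rescales inputs to `[0, 1]`
(`uint8 / 255`; model range `(x+1)/2`). Two constant volumes at the
range extremes score the luminance-only closed form
`C1 / (1 + C1) = 9.999e-5`; random volumes are checked against a
brute-force sliding-window oracle to `1e-6`.
`ssimPairDistributions` computes all real-real and real-generated
pair scores and their shared-edge histograms, reporting the
histogram overlap as a scalar summary.

**Kernel distance** (`kid`) embeds each volume's middle-depth slice,
rescaled to `[0, 1]`, through a pluggable extractor (default: a
fixed 64-dimensional random projection, seeded once so that scores
are comparable across runs) and computes the polynomial-kernel
(`(<x,y>/d + 1)^3`) squared maximum mean discrepancy, averaged over
random subsets (default 10 subsets of 50). Two estimator variants
exist: `mmd2Unbiased` defaults to the standard unbiased form whose
cross term is a full mean; `kid` uses the complete U-statistic
variant (cross-diagonal excluded) with identically-drawn subset
indices on both sides, so a set compared against itself scores
exactly 0 — a property worth the slight variance increase because it
anchors the scale of the curve.

**Snapshot selection** smooths a per-checkpoint KID curve with a
trailing, truncated 5-point moving average and picks the earliest
checkpoint whose smoothed value is within 5% (relative, on the
magnitude of the minimum) of the smoothed global minimum — the
tolerance trades a marginal KID increase for earlier checkpoints,
which tend to be less overfitted.

## Synthetic data

The generator (`generateVolume`, `generateTrainingSet`) produces
stylized, not anatomically faithful, nodules: an ellipsoidal bright
blob with a logistic falloff over a correlated-noise background,
quantized to uint8. Class 1 draws larger radii (0.18-0.30 of the
extent vs 0.10-0.18) and higher peaks (200-250 vs 160-200). The two
classes are separable by a simple intensity-histogram threshold rule
(fraction of voxels at or above 160) with >= 90% accuracy at the
default settings, which is what the metric tests need: structured,
class-conditional volumes with nontrivial frequency content.

What the tests do and do not show: every pipeline stage is validated
for correctness (oracles, closed forms, involutions) and for the
qualitative behaviour expected of it (KID grows with distribution
shift and shrinks monotonically as the generated set is mixed toward
the reals; SSIM overlap is maximal on self-comparison). None of this
certifies performance on real CT data; the synthetic volumes are a
test harness, not a benchmark.

## Problem sizes

Tests and the summary script run on 16^3-32^3 volumes, 8-100 volume
batches, and full 300 kimg controller simulations; everything
completes in minutes on one CPU. The defaults (863/295 roster,
batch 16, 300 kimg, target 0.7, speed 500 kimg, gamma 0.6) are the
study conditions and are exercised as such, not rescaled.

## Limitations

* Augmentation leakage ("non-leaking" requires invertibility of the
  augmentation distribution) is taken from the ADA design, not
  re-proven here.
* The frequency bands use Haar rather than a longer symmetric
  biorthogonal filter; band localization is coarser, in exchange for
  exact orthogonal reconstruction without external dependencies.
* The KID extractor is a random projection, not a pretrained feature
  network; absolute KID values are not comparable to published
  feature-space KIDs, only to other scores from the same extractor.
* The discriminator/generator contracts are toys; integration with a
  real training loop is out of scope.
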