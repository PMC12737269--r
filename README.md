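# ada3d

Adaptive discriminator augmentation (ADA) and evaluation toolkit for
volumetric medical images, in pure R.

## The problem

Generative adversarial networks overfit badly when trained on small
medical imaging datasets: with only a few hundred CT volumes the
discriminator memorizes the training set and synthesis quality
collapses. Adaptive discriminator augmentation counters this by
applying a stochastic, non-leaking augmentation pipeline to every
image the discriminator sees, with a single shared probability `p`
that a feedback controller tunes online from how confidently the
discriminator separates real from fake. Evaluating volumetric
synthesis additionally needs 3D-aware metrics: slice-based scores miss
through-plane artifacts.

This package implements the data-side machinery of that training
recipe for 3D volumes, fully decoupled from any deep-learning
framework:

- **Volume data model** (`VolumeGrid`): depth x height x width arrays
  in uint8 `[0, 255]` or model `[-1, 1]` range, with NPZ and NIfTI
  I/O, trilinear resampling chains, and class-roster balancing.
- **3D augmentation pipeline** (`augmentBatch`): pixel-level flips /
  axial rotations / integer translations, general geometric warps via
  homogeneous 4x4 matrices with inverse-warp trilinear resampling and
  reflection padding, colour transforms through an RGB lift (exact
  no-ops on grayscale for hue/saturation), dyadic frequency-band
  gains via an orthogonal separable wavelet, cutout, and additive
  noise — every transform gated by the shared probability `p`.
- **ADA controller** (`adaState`, `accumulate`, `adjustP`,
  `runController`): tracks an exponential moving average of the sign
  of discriminator logits on reals and nudges `p` toward a target of
  0.7 at a fixed adjustment speed.
- **Regularizer reference semantics** (`r1Penalty`,
  `pathLengthPenalty`): R1 and path-length penalties over explicit
  gradient/vector-Jacobian-product contracts, with the
  `1/sqrt(D*H*W)` volumetric noise normalization.
- **3D metrics** (`ssim3d`, `mmd2Unbiased`, `kid`): full-volume SSIM
  with an 11^3 Gaussian window, unbiased polynomial-kernel MMD^2, a
  subset-averaged kernel distance on middle-depth slices, KID-curve
  smoothing and snapshot selection.
- **Synthetic nodule generator** (`generateVolume`,
  `generateTrainingSet`): class-conditional ellipsoid "nodules" on
  correlated-noise backgrounds, standing in for real CT data so the
  entire pipeline is exercisable at desk scale.
- **CLI** (`inst/cli/ada3d.R`): `synth | augment | eval | select |
  simulate` subcommands, each writing a manifest with the fully
  resolved configuration and seed.

## Worked example

```r
library(ada3d)

# 12 synthetic nodule volumes, 6 per class, 32^3 voxels
ts <- generateTrainingSet(6, 6, extent = 32, seed = 7)
ts$volumes[[1]]
#> VolumeGrid 32 x 32 x 32 [uint8 range], spacing 1 x 1 x 1 mm
#>   intensity: min 0, max 173, mean 48.17

# augment one volume with the full pipeline at p = 0.8
v   <- toModelRange(ts$volumes[[1]])
aug <- augmentBatch(list(v), augConfig("strong"), p = 0.8, seed = 1)[[1]]
ssim3d(v, aug)
#> [1] -0.006349957        # strong geometric warp: structure decorrelated

# simulate the ADA controller against the response model r(p) = 1 - p;
# its fixed point is where 1 - p crosses the 0.7 target, i.e. p = 0.3
traj <- runController(responseModels$linear, trainSchedule(), seed = 42)
mean(traj$p[traj$images_seen > 150000])
#> [1] 0.3021643

# kernel distance between the two synthetic classes, and self-distance
kid(ts$volumes[1:6], ts$volumes[7:12],
    kidConfig(subsetSize = 6, nSubsets = 2), seed = 3)$kid
#> [1] 0.06824208
kid(ts$volumes[1:6], ts$volumes[1:6],
    kidConfig(subsetSize = 6, nSubsets = 2), seed = 3)$kid
#> [1] 0

# balance the default 863/295 class roster by down-sampling
bal <- balanceRoster(makeRoster(863, 295), seed = 42)
c(kept = nrow(bal$roster), removed = bal$removedCount)
#>    kept removed
#>     590     568
```

## Documentation

Function documentation lives as roxygen comments alongside the code
in `R/`. The methods vignette
(`vignettes/ada-augmentation-methods.Rmd`, source only) describes the
augmentation pipeline, controller, regularizer contracts and metrics
in detail, including every default and the numerical choices behind
the geometry and wavelet code.

## License

MIT, see `LICENSE`.
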