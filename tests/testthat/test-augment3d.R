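test_that("p = 0 yields the identity draw and identity batch for every preset", {
  for (preset in c("none", "color_only", "strong")) {
    set.seed(1)
    d <- sampleDraw(augConfig(preset), p = 0)
    expect_true(ada3d:::isIdentityDraw(d))
  }
  vols <- lapply(noduleBatch(3, extent = 16, seed = 7), toModelRange)
  out <- augmentBatch(vols, augConfig("strong"), p = 0, seed = 1)
  for (i in seq_along(vols))
    expect_identical(voxels(out[[i]]), voxels(vols[[i]]))
  # preset "none" is identity at any p
  out2 <- augmentBatch(vols, augConfig("none"), p = 1, seed = 1)
  for (i in seq_along(vols))
    expect_identical(voxels(out2[[i]]), voxels(vols[[i]]))
})

test_that("draw sampling is deterministic and respects category gating", {
  cfg <- augConfig("strong")
  set.seed(42); d1 <- sampleDraw(cfg, 0.7)
  set.seed(42); d2 <- sampleDraw(cfg, 0.7)
  expect_identical(d1, d2)
  expect_error(sampleDraw(cfg, 1.5), "probability")
  # colour-only draws never touch geometry, filter or corruption
  set.seed(3)
  for (i in 1:20) {
    d <- sampleDraw(augConfig("color_only"), p = 1)
    expect_identical(unname(d@geom), diag(4))
    expect_true(all(d@bandGains == 1))
    expect_true(anyNA(d@cutoutCenter))
    expect_equal(d@noiseStd, 0)
  }
})

test_that("lattice transforms are exact: flip involution, 90-degree 4-cycle, translation inverse", {
  v <- toModelRange(generateVolume(noduleSpec(), 32, seed = 5))
  # flip twice restores exactly (matrix route)
  f <- applyGeometric(v, ada3d:::mat4FlipSagittal())
  expect_false(identical(voxels(f), voxels(v)))
  expect_identical(voxels(applyGeometric(f, ada3d:::mat4FlipSagittal())),
                   voxels(v))
  # four quarter-turns restore exactly
  r <- v
  for (i in 1:4) r <- applyGeometric(r, ada3d:::mat4AxialRot(pi / 2))
  expect_identical(voxels(r), voxels(v))
  # 180 degrees equals two quarter-turns (index-permutation oracle)
  r180 <- applyGeometric(v, ada3d:::mat4AxialRot(pi))
  expect_identical(voxels(r180), voxels(rotateAxial90(v, 2L)))
  # integer translation +t then -t restores interior voxels exactly
  t <- c(3, -2, 4)
  tv <- translateInteger(translateInteger(v, t), -t)
  inner <- 5:28
  expect_identical(voxels(tv)[inner, inner, inner],
                   voxels(v)[inner, inner, inner])
})

test_that("matrix warps agree exactly with the index-permutation oracles", {
  v <- toModelRange(generateVolume(noduleSpec(), 16, seed = 9))
  expect_identical(voxels(applyGeometric(v, ada3d:::mat4FlipSagittal())),
                   voxels(flipSagittal(v)))
  for (k in 0:3)
    expect_identical(
      voxels(applyGeometric(v, ada3d:::mat4AxialRot(k * pi / 2))),
      voxels(rotateAxial90(v, k)))
  t <- c(-2, 1, 2)
  expect_identical(
    voxels(applyGeometric(v, ada3d:::mat4Translate(2 * t / 16))),
    voxels(translateInteger(v, t)))
})

test_that("composed geometry equals sequential application on affine fields", {
  v <- affineVolume(32)
  set.seed(21)
  # modest warp, away from borders, so reflection padding never enters
  A <- ada3d:::mat4RandomRotation()
  A[1:3, 1:3] <- diag(3) * 0.9 + 0.1 * A[1:3, 1:3]
  B <- ada3d:::mat4Translate(c(0.05, -0.04, 0.03)) %*%
    ada3d:::mat4Scale(c(1.05, 0.95, 1.02))
  seqPath <- applyGeometric(applyGeometric(v, A), B)
  composed <- applyGeometric(v, B %*% A)
  inner <- 9:24
  expect_lt(max(abs(voxels(seqPath)[inner, inner, inner] -
                    voxels(composed)[inner, inner, inner])), 1e-4)
  expect_error(applyGeometric(v, matrix(0, 4, 4)), "singular")
})

test_that("colour transforms behave as scalar affine maps with exact gray reductions", {
  v <- smoothVolume(16)
  # identity
  expect_identical(voxels(applyColor(v, diag(4))), voxels(v))
  # brightness shifts the mean by exactly b
  b <- 0.2
  vb <- applyColor(v, ada3d:::colorBrightness(b))
  expect_equal(mean(voxels(vb)) - mean(voxels(v)), b, tolerance = 1e-12)
  z <- volumeGrid(array(0, c(8, 8, 8)), "model")
  expect_true(all(abs(voxels(applyColor(z, ada3d:::colorBrightness(0.2))) - 0.2) < 1e-12))
  # contrast scales about 0: a zero-mean volume keeps mean 0
  vc <- replaceMean0 <- ada3d:::replaceVoxels(v, voxels(v) - mean(voxels(v)))
  out <- applyColor(vc, ada3d:::colorContrast(1.7))
  expect_lt(abs(mean(voxels(out))), 1e-12)
  expect_equal(voxels(out), voxels(vc) * 1.7, tolerance = 1e-12)
  # luma flip negates about mid-range 0
  expect_equal(voxels(applyColor(v, ada3d:::colorLumaFlip())), -voxels(v),
               tolerance = 1e-12)
  # hue rotation and saturation are exact no-ops on gray data
  hs <- ada3d:::colorHueRotate(2.1) %*% ada3d:::colorSaturation(3)
  expect_equal(voxels(applyColor(v, hs)), voxels(v), tolerance = 1e-12)
})

test_that("frequency-band filtering reconstructs perfectly at unit gains and inverts gains", {
  v <- toModelRange(generateVolume(noduleSpec(), 32, seed = 13))
  # perfect reconstruction (force the transform; no early return)
  dec <- ada3d:::dwt3(voxels(v), 3L)
  expect_lt(max(abs(ada3d:::idwt3(dec) - voxels(v))), 1e-5)
  # constants live in the lowest band
  const <- volumeGrid(array(0.4, c(16, 16, 16)), "model")
  killed <- applyBandFilter(const, c(1e-15, 1, 1, 1))
  expect_lt(max(abs(voxels(killed))), 1e-9)
  # gain g then 1/g restores
  g <- 2.5
  back <- applyBandFilter(applyBandFilter(v, c(1, g, 1, 1)),
                          c(1, 1 / g, 1, 1))
  expect_lt(max(abs(voxels(back) - voxels(v))), 1e-10)
  # high-band gain zero smooths: residual energy concentrated in details
  lowOnly <- applyBandFilter(v, c(1, 1, 1, 1e-15))
  expect_false(identical(voxels(lowOnly), voxels(v)))
  expect_error(applyBandFilter(volumeGrid(array(0, c(12, 12, 12)), "model"),
                               c(1, 1, 1, 2)), "divisible")
})

test_that("cutout zeroes a half-extent box, clipped at borders", {
  ones <- volumeGrid(array(1, c(32, 32, 32)), "model")
  centred <- applyCutout(ones, c(0.5, 0.5, 0.5))
  expect_equal(sum(voxels(centred) == 0), 16^3)
  corner <- applyCutout(ones, c(0, 0, 0))
  expect_equal(sum(voxels(corner) == 0), 8^3)
  expect_true(all(voxels(corner)[1:8, 1:8, 1:8] == 0))
  # all-zero volume unchanged
  zeros <- volumeGrid(array(0, c(16, 16, 16)), "model")
  expect_identical(voxels(applyCutout(zeros, c(0.3, 0.7, 0.5))),
                   voxels(zeros))
})

test_that("Gaussian noise has the drawn std and zero mean at CLT precision", {
  v <- volumeGrid(array(0, c(32, 32, 32)), "model")
  expect_identical(voxels(applyNoise(v, 0)), voxels(v))
  set.seed(8)
  std <- 0.3
  out <- applyNoise(v, std)
  resid <- voxels(out) - voxels(v)
  expect_lt(abs(mean(resid)), 4 * std / sqrt(length(resid)))
  expect_lt(abs(sd(resid) - std) / std, 0.05)
  expect_error(applyNoise(v, -1), ">=")
})

test_that("batches are deterministic under a seed and reject mixed extents", {
  vols <- lapply(noduleBatch(2, extent = 16, seed = 31), toModelRange)
  o1 <- augmentBatch(vols, augConfig("strong"), 1, seed = 9)
  o2 <- augmentBatch(vols, augConfig("strong"), 1, seed = 9)
  for (i in seq_along(vols))
    expect_identical(voxels(o1[[i]]), voxels(o2[[i]]))
  expect_length(attr(o1, "draws"), length(vols))
  bad <- c(vols, list(toModelRange(generateVolume(noduleSpec(), 32, seed = 1))))
  expect_error(augmentBatch(bad, augConfig("strong"), 0.5), "extent")
})

test_that("pixel-level application is lattice-exact and identity at p = 0", {
  v <- toModelRange(generateVolume(noduleSpec(), 16, seed = 17))
  set.seed(2)
  expect_identical(voxels(applyPixelLevel(v, 0)), voxels(v))
  # at p = 1 the output is some composition of exact index permutations:
  # the multiset of interior voxel values is preserved by flip/rot
  set.seed(4)
  out <- applyPixelLevel(flipSagittal(v), 0)
  expect_equal(sort(as.vector(voxels(out))), sort(as.vector(voxels(v))))
})
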