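test_that("NPZ save/load round-trips voxelwise exactly and matches the declared layout", {
  v <- randomUint8Volume(16, seed = 11)
  path <- withr::local_tempfile(fileext = ".npz")
  saveVolume(v, path, label = 1L)
  v2 <- loadVolume(path)
  expect_identical(voxels(v2), voxels(v))
  expect_equal(intensityRange(v2), "uint8")

  # float volumes round-trip too
  m <- toModelRange(v)
  pathf <- withr::local_tempfile(fileext = ".npz")
  saveVolume(m, pathf)
  m2 <- loadVolume(pathf)
  expect_identical(voxels(m2), voxels(m))
  expect_equal(intensityRange(m2), "model")

  # (1, D, H, W) layout is accepted
  v4 <- volumeGrid(array(voxels(v), c(1, 16, 16, 16)))
  expect_identical(voxels(v4), voxels(v))
})

test_that("NIfTI save/load round-trips voxels and spacing", {
  v <- volumeGrid(voxels(randomUint8Volume(12, seed = 3)),
                  spacing = c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  saveVolume(v, path)
  v2 <- loadVolume(path)
  expect_equal(voxels(v2), voxels(v))
  expect_equal(spacingMm(v2), c(1, 1, 1))
})

test_that("malformed volume input is rejected", {
  expect_error(volumeGrid(matrix(0, 4, 4)), "3D")
  expect_error(volumeGrid(array(0, c(2, 4, 4, 4))), "singleton")
  expect_error(volumeGrid(array(300, c(4, 4, 4)), "uint8"))
  expect_error(loadVolume("/nonexistent/file.npz"), "not found")
  # rank-2 NPZ payload
  path <- withr::local_tempfile(fileext = ".npz")
  ada3d:::zipWrite(path, list("voxels.npy" =
    ada3d:::npySerialize(matrix(0, 4, 4))))
  expect_error(loadVolume(path), "rank")
})

test_that("model-range mapping is the affine x/127.5 - 1 with exact endpoints", {
  lo <- volumeGrid(array(0, c(4, 4, 4)))
  hi <- volumeGrid(array(255, c(4, 4, 4)))
  expect_true(all(voxels(toModelRange(lo)) == -1))
  expect_true(all(voxels(toModelRange(hi)) == 1))
  # values adjacent to 127.5 map near zero
  mid <- volumeGrid(array(c(127, 128), c(4, 4, 4)))
  expect_lt(max(abs(voxels(toModelRange(mid)))), 0.005)
  expect_equal(voxels(toModelRange(mid))[1], 127 / 127.5 - 1)
  # inverse restores within rounding
  v <- randomUint8Volume(8, seed = 5)
  back <- fromModelRange(toModelRange(v))
  expect_lt(max(abs(voxels(back) - voxels(v))), 1 / 255)
  expect_warning(toModelRange(toModelRange(v)), "already")
})

test_that("middle slices sit at floor(n/2), zero-based, on each axis", {
  arr <- array(0, c(32, 32, 32))
  arr[17, 1, 1] <- 9   # zero-based depth index 16
  v <- volumeGrid(arr)
  ms <- middleSlices(v)
  expect_equal(ms$depth[1, 1], 9)
  expect_equal(dim(ms$depth), c(32, 32))
  # odd extent: floor(3/2) = 1 zero-based = index 2
  arr3 <- array(seq_len(27), c(3, 3, 3))
  ms3 <- middleSlices(volumeGrid(arr3 / 27 * 255))
  expect_equal(ms3$depth, arr3[2, , ] / 27 * 255)
  expect_equal(ms3$height, arr3[, 2, ] / 27 * 255)
  expect_equal(ms3$width, arr3[, , 2] / 27 * 255)
})

test_that("the resampling chain reproduces the preprocessing extents and preserves constants", {
  set.seed(7)
  big <- volumeGrid(array(runif(80^3, 0, 255), c(80, 80, 80)))
  out <- resampleChain(big)   # 28 -> 64 -> 32
  expect_equal(extent(out), c(32L, 32L, 32L))

  # identity resample
  v <- randomUint8Volume(16, seed = 2)
  expect_lt(max(abs(voxels(resampleChain(v, stages = 16L)) - voxels(v))),
            1e-5)
  # constants survive any chain exactly
  const <- volumeGrid(array(42, c(24, 24, 24)))
  out2 <- resampleChain(const, stages = c(6L, 17L, 12L))
  expect_equal(max(abs(voxels(out2) - 42)), 0)
  # center crop path
  out3 <- resampleChain(big, centerCrop = 80L)
  expect_equal(voxels(out3), voxels(out))
  expect_error(resampleChain(v, stages = c(8L, -1L)), "positive")
})

test_that("roster balancing removes exactly the majority excess, reproducibly", {
  r <- makeRoster(863, 295)
  b <- balanceRoster(r, seed = 1)
  expect_equal(b$removedCount, 568L)
  expect_equal(nrow(b$roster), 590L)
  expect_equal(unname(table(b$roster$class_label)), c(295L, 295L),
               ignore_attr = TRUE)
  # reproducible; union of kept and removed is the input
  b2 <- balanceRoster(r, seed = 1)
  expect_identical(b$roster, b2$roster)
  expect_setequal(c(b$roster$volume_id, b$removed$volume_id),
                  r$volume_id)
  b3 <- balanceRoster(r, seed = 2)
  expect_false(identical(b3$removed$volume_id, b$removed$volume_id))

  # already balanced and small cases
  expect_equal(balanceRoster(makeRoster(3, 3), 1)$removedCount, 0L)
  s <- balanceRoster(makeRoster(10, 3), 1)
  expect_equal(s$removedCount, 7L)
  expect_equal(nrow(s$roster), 6L)
  expect_error(balanceRoster(makeRoster(5, 0), 1), "both classes")
})

test_that("roster CSV round-trips", {
  r <- makeRoster(4, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRoster(r, path)
  expect_identical(readRoster(path), r)
})
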