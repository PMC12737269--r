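test_that("the polynomial kernel evaluates (x.y/d + 1)^3", {
  expect_equal(polyKernel(rep(0, 4), rep(0, 4)), 1)
  x <- rep(1, 8)
  expect_equal(polyKernel(x, x), 8)   # <x,x> = d -> (1+1)^3
  set.seed(2)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(polyKernel(a, b), (sum(a * b) / 6 + 1)^3)
  expect_error(polyKernel(a, rnorm(5)), "dimension")
})

test_that("unbiased MMD^2 equals the double-loop oracle and is permutation invariant", {
  set.seed(10)
  X <- matrix(rnorm(10 * 4), 10, 4)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  expect_equal(mmd2Unbiased(X, Y), mmd2LoopOracle(X, Y), tolerance = 1e-12)
  # X = Y as multisets, full-cross-mean form, against the loop oracle
  expect_equal(mmd2Unbiased(X, X), mmd2LoopOracle(X, X), tolerance = 1e-12)
  # permutation invariance within each set
  expect_equal(mmd2Unbiased(X[sample(10), ], Y[sample(12), ]),
               mmd2Unbiased(X, Y), tolerance = 1e-12)
  # degenerate equal-point sets: exactly zero
  a <- matrix(rep(c(1, 2, 3), 2), 2, 3, byrow = TRUE)
  expect_equal(mmd2Unbiased(a, a), 0)
  # the U-statistic variant matches its oracle and zeroes identical sets
  Y2 <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(mmd2Unbiased(X, Y2, uStatistic = TRUE),
               mmd2LoopOracle(X, Y2, uStatistic = TRUE), tolerance = 1e-12)
  expect_equal(mmd2Unbiased(X, X, uStatistic = TRUE), 0)
  expect_error(mmd2Unbiased(X[1:2, ], Y[1, , drop = FALSE]), "two samples")
})

test_that("the MMD null is centred and the estimator detects large shifts", {
  fc <- generateFeatureClouds(500, 500, dim = 16, shift = 0, seed = 5)
  est <- mmd2Unbiased(fc$real, fc$gen)
  # permutation-based null spread at the same sample size
  pooled <- rbind(fc$real, fc$gen)
  set.seed(99)
  nulls <- replicate(40, {
    idx <- sample(nrow(pooled))
    mmd2Unbiased(pooled[idx[1:500], ], pooled[idx[501:1000], ])
  })
  se <- sd(nulls)
  expect_lt(abs(est), 3 * se)
  # a 5-sigma mean shift is detected far beyond the null spread
  fc5 <- generateFeatureClouds(500, 500, dim = 16, shift = 5, seed = 5)
  expect_gt(mmd2Unbiased(fc5$real, fc5$gen), 5 * se)
})

test_that("KID is zero on self-comparison and equals the single-subset oracle", {
  vols <- noduleBatch(4, extent = 16, seed = 70)   # 8 volumes
  cfgFull <- kidConfig(subsetSize = 8, nSubsets = 1,
                       extractor = rawPixelExtractor())
  self <- kid(vols, vols, cfgFull, seed = 1)
  expect_lt(abs(self$kid), 1e-9)
  # oracle equivalence: subset = whole set, raw-pixel features
  others <- noduleBatch(4, extent = 16, seed = 80)
  k <- kid(vols, others, cfgFull, seed = 1)
  X <- t(sapply(vols, function(v) as.numeric(middleSlices(v)$depth) / 255))
  Y <- t(sapply(others, function(v) as.numeric(middleSlices(v)$depth) / 255))
  expect_equal(k$kid, mmd2LoopOracle(X, Y, uStatistic = TRUE),
               tolerance = 1e-10)
  expect_length(k$perSubset, 1)
})

test_that("KID increases under intensity shift and decreases along mixing toward the reals", {
  vols <- lapply(noduleBatch(4, extent = 16, seed = 90), toModelRange)
  cfg <- kidConfig(subsetSize = 8, nSubsets = 1)
  base <- kid(vols, vols, cfg, seed = 1)$kid
  shifted <- lapply(vols, function(v)
    ada3d:::replaceVoxels(v, pmin(voxels(v) + 0.5, 1)))
  kShift <- kid(vols, shifted, cfg, seed = 1)$kid
  expect_gt(kShift, base)
  # interpolating the generated set toward the reals shrinks KID
  mix <- function(lam) lapply(seq_along(vols), function(i)
    ada3d:::replaceVoxels(vols[[i]],
      (1 - lam) * voxels(shifted[[i]]) + lam * voxels(vols[[i]])))
  ks <- vapply(c(0, 0.5, 1), function(l)
    kid(vols, mix(l), cfg, seed = 1)$kid, numeric(1))
  expect_true(all(diff(ks) < 0))
})

test_that("per-class KID averages the two class scores", {
  vols <- noduleBatch(4, extent = 16, seed = 100)
  roster <- makeRoster(4, 4)
  cfg <- kidConfig(subsetSize = 4, nSubsets = 1)
  r <- kidPerClass(vols, vols, roster, roster, cfg, seed = 2)
  expect_equal(r$kid_mean, (r$kid_class0 + r$kid_class1) / 2)
  expect_lt(abs(r$kid_class0), 1e-9)
  expect_lt(abs(r$kid_class1), 1e-9)
})

test_that("curve smoothing is a trailing truncated window-5 average", {
  cur <- data.frame(kimg = 1:5, kid_class0 = c(5, 4, 3, 2, 1),
                    kid_class1 = c(5, 4, 3, 2, 1))
  sm <- smoothKidCurve(cur)
  expect_equal(sm$kid_smooth, c(5, 4.5, 4, 3.5, 3))
  # constant curve is unchanged
  const <- data.frame(kimg = seq(4, 40, 4), kid_class0 = 2, kid_class1 = 4)
  expect_true(all(smoothKidCurve(const)$kid_smooth == 3))
  # single record is itself
  one <- data.frame(kimg = 4, kid_class0 = 7, kid_class1 = 7)
  expect_equal(smoothKidCurve(one)$kid_smooth, 7)
  expect_error(smoothKidCurve(data.frame(kimg = c(2, 1),
                                         kid_class0 = 1:2,
                                         kid_class1 = 1:2)),
               "increasing")
})

test_that("snapshot selection takes the earliest value within 5% of the smoothed minimum", {
  # strictly decreasing, last two within 5%: the earlier one wins
  cur <- data.frame(kimg = 1:3, kid_mean = c(10, 2.04, 2))
  cur$kid_class0 <- cur$kid_mean; cur$kid_class1 <- cur$kid_mean
  sm <- smoothKidCurve(cur, window = 1L)   # no smoothing: test selection
  sel <- selectBestSnapshot(sm)
  expect_equal(sel$kimg, 2)
  # unique sharp minimum
  cur2 <- data.frame(kimg = 1:4, kid_mean = c(9, 8, 1, 8))
  cur2$kid_class0 <- cur2$kid_mean; cur2$kid_class1 <- cur2$kid_mean
  expect_equal(selectBestSnapshot(smoothKidCurve(cur2, 1L))$kimg, 3)
  # constant series: first checkpoint
  cur3 <- data.frame(kimg = c(4, 8, 12), kid_mean = 5,
                     kid_class0 = 5, kid_class1 = 5)
  expect_equal(selectBestSnapshot(cur3)$kimg, 4)
  # never later than the smoothed argmin
  set.seed(3)
  for (i in 1:10) {
    k <- abs(rnorm(20)) + 0.1
    cur4 <- data.frame(kimg = 1:20, kid_class0 = k, kid_class1 = k)
    sm4 <- smoothKidCurve(cur4)
    sel4 <- selectBestSnapshot(sm4)
    expect_lte(sel4$index, which.min(sm4$kid_smooth))
  }
})

test_that("KID-curve CSV round-trips with the derived mean column", {
  cur <- data.frame(kimg = c(4, 8), kid_class0 = c(1, 2),
                    kid_class1 = c(3, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  writeKidCurve(cur, path)
  back <- readKidCurve(path)
  expect_equal(back$kid_mean, c(2, 3))
  expect_equal(back$kimg, cur$kimg)
})
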