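# Shared fixtures, all generated in code.

# a smooth model-range volume: trilinear interpolation reproduces
# affine fields exactly, so geometric-composition checks on it isolate
# convention errors from interpolation error
affineVolume <- function(n = 32) {
  x <- (2 * seq_len(n) - n - 1) / n
  arr <- 0.2 * outer(outer(x, rep(1, n)), rep(1, n)) +
    0.3 * outer(outer(rep(1, n), x), rep(1, n)) -
    0.1 * outer(outer(rep(1, n), rep(1, n)), x)
  volumeGrid(arr, "model")
}

# a band-limited smooth volume with genuine 3D structure
smoothVolume <- function(n = 32) {
  x <- (2 * seq_len(n) - n - 1) / n
  arr <- 0.4 * outer(outer(sin(pi * x), cos(pi * x)), sin(pi * x)) +
    0.2 * outer(outer(cos(pi * x), rep(1, n)), cos(pi * x))
  volumeGrid(arr, "model")
}

randomUint8Volume <- function(n = 16, seed = 1) {
  set.seed(seed)
  volumeGrid(array(sample(0:255, n^3, replace = TRUE), c(n, n, n)))
}

noduleBatch <- function(nPerClass = 4, extent = 16, seed = 100) {
  set.seed(seed)
  c(lapply(seq_len(nPerClass), function(i)
      generateVolume(ada3d:::drawSpec(0L), extent, seed = seed + i)),
    lapply(seq_len(nPerClass), function(i)
      generateVolume(ada3d:::drawSpec(1L), extent, seed = seed + 50 + i)))
}

# O(n^2) double-loop MMD^2 oracle, independent of the matrix route
mmd2LoopOracle <- function(X, Y, degree = 3, offset = 1,
                           uStatistic = FALSE) {
  m <- nrow(X); n <- nrow(Y)
  k <- function(a, b) (sum(a * b) / length(a) + offset)^degree
  kxx <- 0; kyy <- 0; kxy <- 0; kxyDiag <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) kxx <- kxx + k(X[i, ], X[j, ])
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) kyy <- kyy + k(Y[i, ], Y[j, ])
  for (i in seq_len(m)) for (j in seq_len(n)) {
    v <- k(X[i, ], Y[j, ])
    kxy <- kxy + v
    if (i == j) kxyDiag <- kxyDiag + v
  }
  within <- kxx / (m * (m - 1)) + kyy / (n * (n - 1))
  if (uStatistic) within - 2 * (kxy - kxyDiag) / (m * (m - 1))
  else within - 2 * kxy / (m * n)
}

# brute-force sliding-window SSIM oracle on [0, 1]-scaled arrays
ssimBruteOracle <- function(x, y, win = 11, sigma = 1.5,
                            C1 = 1e-4, C2 = 9e-4) {
  g1 <- exp(-(seq_len(win) - (win + 1) / 2)^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  w <- outer(outer(g1, g1), g1)
  n <- dim(x)[1]
  nv <- n - win + 1
  vals <- numeric(nv^3)
  idx <- 1
  for (i in seq_len(nv)) for (j in seq_len(nv)) for (k in seq_len(nv)) {
    wx <- x[i:(i + win - 1), j:(j + win - 1), k:(k + win - 1)]
    wy <- y[i:(i + win - 1), j:(j + win - 1), k:(k + win - 1)]
    mx <- sum(w * wx); my <- sum(w * wy)
    sxx <- sum(w * wx^2) - mx^2
    syy <- sum(w * wy^2) - my^2
    sxy <- sum(w * wx * wy) - mx * my
    vals[idx] <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
      ((mx^2 + my^2 + C1) * (sxx + syy + C2))
    idx <- idx + 1
  }
  mean(vals)
}
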