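# Application of sampled augmentation draws to volumes.
#
# Geometry acts about the volume centre in normalized [-1,1]^3
# coordinates (align-corners-off: voxel centre i+0.5 of an n-voxel axis
# sits at (2i+1)/n - 1).  Out-of-volume samples use reflection padding.

# reflect integer indices into [1, n] (half-sample symmetric)
reflectIndex <- function(j, n) {
  p <- (j - 1L) %% (2L * n)
  p <- ifelse(p < 0L, p + 2L * n, p)
  ifelse(p < n, p + 1L, 2L * n - p)
}

#' Apply a homogeneous geometric transform to a volume
#'
#' Inverse-warp resampling: each output voxel centre is mapped through
#' `solve(geom)` and the input is sampled there with trilinear
#' interpolation and reflection padding.  Lattice-exact transforms
#' (flips, 90-degree axial rotations, integer translations) produce
#' interpolation weights of exactly 0/1, so they round-trip voxelwise
#' exactly; the identity matrix returns the input unchanged.
#'
#' @param v a [VolumeGrid-class] in model range.
#' @param geom invertible 4x4 matrix on normalized coordinates.
#' @return the warped [VolumeGrid-class].
#' @export
applyGeometric <- function(v, geom) {
  stopifnot(is(v, "VolumeGrid"))
  if (v@intensityRange != RANGE_MODEL)
    stop("geometric warps require model-range intensities")
  if (abs(det(geom)) < 1e-12) stop("geometry matrix is singular")
  if (identical(unname(geom), diag(4))) return(v)
  d <- dim(v@voxels)
  inv <- solve(geom)
  # normalized output coordinates of every voxel centre
  coord1 <- (2 * seq_len(d[1]) - d[1] - 1) / d[1]
  coord2 <- (2 * seq_len(d[2]) - d[2] - 1) / d[2]
  coord3 <- (2 * seq_len(d[3]) - d[3] - 1) / d[3]
  n <- prod(d)
  g <- cbind(rep(coord1, times = d[2] * d[3]),
             rep(rep(coord2, each = d[1]), times = d[3]),
             rep(coord3, each = d[1] * d[2]),
             1)
  src <- g %*% t(inv)
  arr <- v@voxels
  out <- numeric(n)
  wTot <- 0
  idx <- list(); frac <- list()
  for (ax in 1:3) {
    ci <- (src[, ax] + 1) / 2 * d[ax] + 0.5  # continuous 1-based index
    snap <- abs(ci - round(ci)) < 1e-9
    ci[snap] <- round(ci[snap])
    i0 <- floor(ci)
    idx[[ax]] <- i0
    frac[[ax]] <- ci - i0
  }
  for (corner in 0:7) {
    b <- c(corner %% 2, corner %/% 2 %% 2, corner %/% 4)
    w <- rep(1, n)
    lin <- rep(1, n)
    stride <- c(1, d[1], d[1] * d[2])
    skip <- FALSE
    for (ax in 1:3) {
      wAx <- if (b[ax + 0] == 0) 1 - frac[[ax]] else frac[[ax]]
      w <- w * wAx
      j <- reflectIndex(idx[[ax]] + b[ax], d[ax])
      lin <- lin + (j - 1) * stride[ax]
    }
    if (any(w != 0)) out <- out + w * arr[lin]
  }
  dim(out) <- d
  replaceVoxels(v, out)
}

## --- lattice-exact pixel-level primitives ------------------------

#' Lattice-exact pixel-level edits
#'
#' `flipSagittal()` mirrors along the sagittal (width) axis;
#' `rotateAxial90()` rotates `k` times by 90 degrees in the axial
#' (height--width) plane; `translateInteger()` shifts by whole voxels
#' with reflection padding.  All three are pure index permutations
#' (no interpolation) and agree exactly with [applyGeometric()] given
#' the corresponding matrices.  `applyPixelLevel()` samples each of the
#' three with probability `p` from the current RNG stream and applies
#' them.
#'
#' @param v a [VolumeGrid-class].
#' @return the edited [VolumeGrid-class].
#' @export
flipSagittal <- function(v) {
  stopifnot(is(v, "VolumeGrid"))
  n <- dim(v@voxels)[3]
  replaceVoxels(v, v@voxels[, , n:1, drop = FALSE])
}

#' @rdname flipSagittal
#' @param k number of 90-degree rotations (any integer).
#' @export
rotateAxial90 <- function(v, k = 1L) {
  stopifnot(is(v, "VolumeGrid"))
  d <- dim(v@voxels)
  if (d[2] != d[3])
    stop("axial 90-degree rotation needs square height/width")
  arr <- v@voxels
  k <- ((k %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) {
    n <- dim(arr)[3]
    arr <- aperm(arr[, , n:1, drop = FALSE], c(1, 3, 2))
  }
  replaceVoxels(v, arr)
}

#' @rdname flipSagittal
#' @param t integer voxel shift per axis (D, H, W).
#' @export
translateInteger <- function(v, t) {
  stopifnot(is(v, "VolumeGrid"), length(t) == 3L,
            all(t == round(t)))
  d <- dim(v@voxels)
  i1 <- reflectIndex(seq_len(d[1]) - t[1], d[1])
  i2 <- reflectIndex(seq_len(d[2]) - t[2], d[2])
  i3 <- reflectIndex(seq_len(d[3]) - t[3], d[3])
  replaceVoxels(v, v@voxels[i1, i2, i3, drop = FALSE])
}

#' @rdname flipSagittal
#' @param p activation probability of each edit.
#' @param intTranslateFrac maximum integer shift as a fraction of each
#'   extent.
#' @export
applyPixelLevel <- function(v, p, intTranslateFrac = 0.125) {
  stopifnot(is(v, "VolumeGrid"))
  if (runif(1) < p) v <- flipSagittal(v)
  if (runif(1) < p) v <- rotateAxial90(v, sample(0:3, 1))
  if (runif(1) < p) {
    tmax <- floor(dim(v@voxels) * intTranslateFrac)
    t <- vapply(tmax, function(m) sample(seq(-m, m), 1), numeric(1))
    v <- translateInteger(v, t)
  }
  v
}

#' Apply a homogeneous colour transform
#'
#' Each voxel's scalar value is lifted to a gray RGB triple,
#' transformed by the 4x4 colour matrix and projected back by the luma
#' weights.  All colour factors used here map gray to gray, so the
#' lift/projection is exact: brightness adds its offset, contrast
#' scales about mid-range 0, luma inversion negates, and hue rotation
#' and saturation reduce to the identity (zero chroma).
#'
#' @param v a [VolumeGrid-class] in model range.
#' @param color 4x4 homogeneous colour matrix.
#' @return the transformed [VolumeGrid-class].
#' @export
applyColor <- function(v, color) {
  stopifnot(is(v, "VolumeGrid"), all(dim(color) == c(4, 4)))
  if (v@intensityRange != RANGE_MODEL)
    stop("colour transforms require model-range intensities")
  if (identical(unname(color), diag(4))) return(v)
  # gray input (x, x, x, 1): projected output is affine in x
  a <- mean(rowSums(color[1:3, 1:3]))
  b <- mean(color[1:3, 4])
  replaceVoxels(v, a * v@voxels + b)
}

## --- frequency-band filter (multi-level separable Haar) ----------

# one Haar analysis/synthesis step along a given axis
haarAxis <- function(arr, ax, inverse = FALSE, detail = NULL) {
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, da[1], prod(da[-1]))
  s <- sqrt(2)
  if (!inverse) {
    odd <- m[seq(1, da[1], 2), , drop = FALSE]
    even <- m[seq(2, da[1], 2), , drop = FALSE]
    lo <- (odd + even) / s
    hi <- (odd - even) / s
    back <- function(x) aperm(array(x, c(da[1] / 2, da[2], da[3])),
                              order(perm))
    list(lo = back(lo), hi = back(hi))
  } else {
    dHi <- aperm(detail, perm)
    h <- matrix(dHi, da[1], prod(da[-1]))
    out <- matrix(0, 2 * da[1], ncol(m))
    out[seq(1, 2 * da[1], 2), ] <- (m + h) / s
    out[seq(2, 2 * da[1], 2), ] <- (m - h) / s
    aperm(array(out, c(2 * da[1], da[2], da[3])), order(perm))
  }
}

# full-level 3D analysis: returns approx + per-level list of 7 detail
# subbands (keyed by the axes that took the high-pass branch)
dwt3 <- function(arr, levels) {
  details <- vector("list", levels)
  a <- arr
  for (l in seq_len(levels)) {
    s1 <- haarAxis(a, 1)
    bands <- list(l = s1$lo, h = s1$hi)
    bands <- lapply(bands, function(b) {
      s2 <- haarAxis(b, 2); list(l = s2$lo, h = s2$hi)
    })
    flat <- list()
    for (n1 in c("l", "h")) for (n2 in c("l", "h")) {
      s3 <- haarAxis(bands[[n1]][[n2]], 3)
      flat[[paste0(n1, n2, "l")]] <- s3$lo
      flat[[paste0(n1, n2, "h")]] <- s3$hi
    }
    a <- flat[["lll"]]
    details[[l]] <- flat[names(flat) != "lll"]
  }
  list(approx = a, details = details)
}

idwt3 <- function(dec) {
  a <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    d <- dec$details[[l]]
    merge3 <- function(n1, n2)
      haarAxis(if (n1 == "l" && n2 == "l") a else d[[paste0(n1, n2, "l")]],
               3, inverse = TRUE, detail = d[[paste0(n1, n2, "h")]])
    m2 <- function(n1)
      haarAxis(merge3(n1, "l"), 2, inverse = TRUE, detail = merge3(n1, "h"))
    a <- haarAxis(m2("l"), 1, inverse = TRUE, detail = m2("h"))
  }
  a
}

#' Scale dyadic frequency bands of a volume
#'
#' Separable multi-level Haar wavelet decomposition along all three
#' axes into dyadic bands — the final approximation (lowest
#' frequencies) plus one detail band per level, coarse to fine.  Each
#' band is multiplied by its gain and the volume is reconstructed; the
#' transform is orthogonal, so unit gains reproduce the input exactly
#' and energy is preserved band by band.
#'
#' @param v a [VolumeGrid-class]; the (cubic) extent must be divisible
#'   by `2^(length(bandGains) - 1)`.
#' @param bandGains positive gains, lowest band first (default length
#'   4 = 3 decomposition levels).
#' @return the filtered [VolumeGrid-class].
#' @export
applyBandFilter <- function(v, bandGains) {
  stopifnot(is(v, "VolumeGrid"))
  if (any(bandGains <= 0)) stop("band gains must be > 0")
  levels <- length(bandGains) - 1L
  if (levels < 1L) stop("need at least two bands")
  d <- dim(v@voxels)
  if (any(d %% 2^levels != 0))
    stop("extent not divisible by 2^levels; cannot decompose to depth ",
         levels)
  if (all(bandGains == 1)) return(v)
  dec <- dwt3(v@voxels, levels)
  dec$approx <- dec$approx * bandGains[1]
  # details[[1]] is the finest level -> highest band (last gain)
  for (l in seq_len(levels)) {
    g <- bandGains[levels - l + 2L]
    dec$details[[l]] <- lapply(dec$details[[l]], function(b) b * g)
  }
  replaceVoxels(v, idwt3(dec))
}

#' Cut out a centred box of a volume
#'
#' Sets an axis-aligned box with edge one-half of each extent, centred
#' at the given fractional coordinates and clipped at the borders, to 0
#' (mid-gray in model range).
#'
#' @param v a [VolumeGrid-class].
#' @param center fractional coordinates in \[0,1\]^3.
#' @param frac box edge as a fraction of each extent (default 1/2).
#' @return the corrupted [VolumeGrid-class].
#' @export
applyCutout <- function(v, center, frac = 0.5) {
  stopifnot(is(v, "VolumeGrid"), length(center) == 3L,
            all(center >= 0 & center <= 1))
  d <- dim(v@voxels)
  size <- floor(d * frac)
  lo0 <- round(center * d - size / 2)
  lo <- pmax(lo0, 0)
  hi <- pmin(lo0 + size, d)
  arr <- v@voxels
  if (all(hi > lo))
    arr[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- 0
  replaceVoxels(v, arr)
}

#' Add i.i.d. Gaussian noise to a volume
#'
#' @param v a [VolumeGrid-class] in model range.
#' @param noiseStd noise standard deviation (>= 0).
#' @return the noisy [VolumeGrid-class].
#' @export
applyNoise <- function(v, noiseStd) {
  stopifnot(is(v, "VolumeGrid"))
  if (noiseStd < 0) stop("noiseStd must be >= 0")
  if (noiseStd == 0) return(v)
  replaceVoxels(v, v@voxels + rnorm(length(v@voxels), 0, noiseStd))
}

#' Apply one sampled draw to a volume
#'
#' Application order: pixel-level/geometric warp, colour, frequency
#' filter, cutout, noise.
#'
#' @param v a [VolumeGrid-class] in model range.
#' @param draw an [AugDraw-class].
#' @return the augmented [VolumeGrid-class].
#' @export
applyDraw <- function(v, draw) {
  stopifnot(is(v, "VolumeGrid"), is(draw, "AugDraw"))
  v <- applyGeometric(v, draw@geom)
  v <- applyColor(v, draw@color)
  if (!all(draw@bandGains == 1)) v <- applyBandFilter(v, draw@bandGains)
  if (!anyNA(draw@cutoutCenter)) v <- applyCutout(v, draw@cutoutCenter)
  if (draw@noiseStd > 0) v <- applyNoise(v, draw@noiseStd)
  v
}

#' Augment a batch of volumes
#'
#' Samples an independent [AugDraw-class] per volume at the shared
#' probability `p` and applies it.  With `p = 0` every volume is
#' returned voxelwise unchanged.
#'
#' @param batch list of model-range [VolumeGrid-class] objects sharing
#'   one extent.
#' @param cfg an [AugConfig-class].
#' @param p shared activation probability.
#' @param seed optional integer; when given, the batch is augmented
#'   under a private RNG stream so repeat calls are identical.
#' @return list of augmented volumes; the per-volume draws are attached
#'   as `attr(, "draws")`.
#' @export
augmentBatch <- function(batch, cfg, p, seed = NULL) {
  stopifnot(is.list(batch), length(batch) > 0, is(cfg, "AugConfig"))
  ext <- dim(batch[[1]]@voxels)
  for (v in batch) {
    if (!is(v, "VolumeGrid")) stop("batch must contain VolumeGrid objects")
    if (!identical(dim(v@voxels), ext))
      stop("all volumes in a batch must share one extent")
    if (v@intensityRange != RANGE_MODEL)
      stop("augmentation operates on model-range volumes")
  }
  run <- function() {
    draws <- lapply(batch, function(v) sampleDraw(cfg, p, extent = ext))
    out <- mapply(applyDraw, batch, draws, SIMPLIFY = FALSE)
    attr(out, "draws") <- draws
    out
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}
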