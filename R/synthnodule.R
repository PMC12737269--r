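# Synthetic nodule-volume generator: stylized stand-in for small
# lung-CT nodule crops (32^3 grayscale cubes, intensities 0-255, a
# bright roughly-ellipsoidal lesion on correlated noisy background).
# Not anatomically faithful; its job is to provide structured,
# class-conditional volumes with nontrivial frequency content so every
# pipeline stage can be exercised and tested at desk scale.

#' Specification of one synthetic nodule volume
#'
#' @param center nodule centre in fractional coordinates (0, 1)^3.
#' @param radii ellipsoid semi-axes as fractions of the extent, each in
#'   (0, 0.5).
#' @param peak nodule peak intensity (uint8, <= 255).
#' @param bgLevel mean background intensity (uint8).
#' @param bgTexture std of the correlated background texture.
#' @param noiseStd std of the iid acquisition-like noise.
#' @param softness logistic falloff width of the nodule boundary, in
#'   units of the (normalized) ellipsoidal radius.
#' @param classLabel 0 or 1.
#' @return a `NoduleSpec` list.
#' @export
noduleSpec <- function(center = c(0.5, 0.5, 0.5),
                       radii = c(0.15, 0.15, 0.15),
                       peak = 200, bgLevel = 60, bgTexture = 20,
                       noiseStd = 8, softness = 0.15,
                       classLabel = 0L) {
  if (any(radii <= 0) || any(radii >= 0.5))
    stop("radii must lie in (0, 0.5)")
  if (peak > 255 || peak < 0) stop("peak must be a uint8 intensity")
  stopifnot(classLabel %in% c(0L, 1L))
  structure(list(center = center, radii = radii, peak = peak,
                 bgLevel = bgLevel, bgTexture = bgTexture,
                 noiseStd = noiseStd, softness = softness,
                 classLabel = as.integer(classLabel)),
            class = "NoduleSpec")
}

# separable Gaussian smoothing with reflected borders (for the
# correlated background texture)
smooth3 <- function(arr, sigma) {
  size <- 2L * ceiling(2 * sigma) + 1L
  g <- gaussian1d(size, sigma)
  half <- (size - 1L) %/% 2L
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    idx <- reflectIndex(seq(1L - half, n + half), n)
    W <- matrix(0, n, length(idx))
    for (i in seq_len(n)) W[i, i:(i + size - 1L)] <- g
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    padded <- matrix(a, da[1], prod(da[-1]))[idx, , drop = FALSE]
    out <- W %*% padded
    arr <- aperm(array(out, da), order(perm))
  }
  arr
}

#' Generate one synthetic nodule volume
#'
#' A smooth bright ellipsoidal blob with a soft (logistic) boundary
#' falloff, added to a correlated-noise background (Gaussian-smoothed
#' white noise) plus iid noise, quantized to uint8 0--255.
#' Deterministic per (spec, seed).
#'
#' @param spec a [noduleSpec()].
#' @param extent cubic edge length (default 32, minimum 8).
#' @param seed integer seed.
#' @return a uint8 [VolumeGrid-class].
#' @export
generateVolume <- function(spec, extent = 32L, seed = 1L) {
  stopifnot(inherits(spec, "NoduleSpec"))
  if (extent < 8L) stop("extent must be at least 8")
  n <- as.integer(extent)
  coords <- (seq_len(n) - 0.5) / n
  d2 <- outer(outer(((coords - spec$center[1]) / spec$radii[1])^2,
                    ((coords - spec$center[2]) / spec$radii[2])^2, "+"),
              ((coords - spec$center[3]) / spec$radii[3])^2, "+")
  nodule <- spec$peak / (1 + exp((sqrt(d2) - 1) / spec$softness))
  withSeed(seed, {
    bg <- smooth3(array(rnorm(n^3), c(n, n, n)), sigma = 1.5)
    bg <- spec$bgLevel + bg / max(sd(bg), 1e-12) * spec$bgTexture
    arr <- pmax(nodule, bg) + rnorm(n^3, 0, spec$noiseStd)
  })
  arr <- round(pmin(pmax(arr, 0), 255))
  volumeGrid(arr, intensityRange = "uint8")
}

# class-conditional spec distributions: malignant-leaning nodules
# (class 1) are larger, brighter, more anisotropic
drawSpec <- function(classLabel) {
  if (classLabel == 0L) {
    radii <- runif(3, 0.10, 0.18)
    peak <- runif(1, 160, 200)
  } else {
    radii <- runif(3, 0.18, 0.30)
    peak <- runif(1, 200, 250)
  }
  noduleSpec(center = pmin(pmax(rnorm(3, 0.5, 0.04), 0.3), 0.7),
             radii = radii, peak = peak,
             bgLevel = runif(1, 40, 80), bgTexture = runif(1, 15, 25),
             noiseStd = 8, classLabel = classLabel)
}

#' Generate a class-labelled synthetic training set
#'
#' Emulates the composition of the lung-nodule training split (863
#' benign-leaning and 295 malignant-leaning volumes by default) with
#' class-conditional nodule morphology.  Fixed seed gives identical
#' roster ordering and volumes.
#'
#' @param nClass0,nClass1 per-class volume counts.
#' @param extent cubic edge length.
#' @param seed integer seed.
#' @return a list with `volumes` (list of [VolumeGrid-class]) and
#'   `roster` (see [makeRoster()]).
#' @export
generateTrainingSet <- function(nClass0 = 863L, nClass1 = 295L,
                                extent = 32L, seed = 1L) {
  stopifnot(nClass0 >= 0, nClass1 >= 0)
  roster <- makeRoster(nClass0, nClass1)
  volumes <- withSeed(seed, lapply(seq_len(nrow(roster)), function(i) {
    spec <- drawSpec(roster$class_label[i])
    generateVolume(spec, extent,
                   seed = sample.int(.Machine$integer.max, 1))
  }))
  list(volumes = volumes, roster = roster)
}

#' Gaussian feature clouds for metric calibration
#'
#' Two Gaussian point clouds in `dim` dimensions whose means differ by
#' `shift` along the first coordinate — the null (`shift = 0`) and
#' alternative cases used to calibrate the MMD estimator and check
#' that the kernel distance responds to distribution shift.
#'
#' @param nReal,nGen cloud sizes.
#' @param dim feature dimension.
#' @param shift mean offset of the second cloud (in units of the unit
#'   std).
#' @param seed integer seed.
#' @return a list with matrices `real` and `gen`.
#' @export
generateFeatureClouds <- function(nReal, nGen, dim = 16L, shift = 0,
                                  seed = 1L) {
  stopifnot(nReal > 0, nGen > 0, dim > 0)
  withSeed(seed, {
    real <- matrix(rnorm(nReal * dim), nReal, dim)
    gen <- matrix(rnorm(nGen * dim), nGen, dim)
    gen[, 1] <- gen[, 1] + shift
    list(real = real, gen = gen)
  })
}
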