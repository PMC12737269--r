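#' Polynomial kernel
#'
#' `k(x, y) = (<x, y> / d + offset)^degree` with `d` the feature
#' dimension — the kernel under which the kernel distance (KID) is the
#' squared maximum mean discrepancy.
#'
#' @param x,y numeric feature vectors of equal dimension.
#' @param degree,offset kernel parameters (defaults 3 and 1).
#' @return the scalar kernel value.
#' @export
polyKernel <- function(x, y, degree = 3, offset = 1) {
  if (length(x) != length(y))
    stop("feature vectors must have equal dimension")
  (sum(x * y) / length(x) + offset)^degree
}

# full kernel matrix between the rows of X and Y
polyKernelMatrix <- function(X, Y, degree = 3, offset = 1) {
  (tcrossprod(X, Y) / ncol(X) + offset)^degree
}

#' Unbiased squared maximum mean discrepancy
#'
#' The standard unbiased MMD^2 estimator between two samples of
#' feature vectors: the off-diagonal mean of the within-X kernel
#' matrix, plus the off-diagonal mean of the within-Y kernel matrix,
#' minus twice the full cross mean.  Being unbiased, the estimate can
#' be negative when the distributions coincide.
#'
#' @param X,Y matrices of feature vectors (rows = samples, at least 2
#'   each; equal column counts).
#' @param degree,offset polynomial kernel parameters.
#' @param uStatistic if TRUE (requires equal sample counts), the cross
#'   term also drops its diagonal and uses the `m (m - 1)` denominator
#'   — the complete-U-statistic variant, which scores two identical,
#'   identically ordered samples as exactly 0.  The default keeps the
#'   full cross mean.  Both forms are unbiased for independent samples.
#' @return the scalar estimate.
#' @export
mmd2Unbiased <- function(X, Y, degree = 3, offset = 1,
                         uStatistic = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2L || nrow(Y) < 2L)
    stop("MMD^2 needs at least two samples per set")
  if (ncol(X) != ncol(Y)) stop("feature dimensions differ")
  m <- nrow(X); n <- nrow(Y)
  Kxx <- polyKernelMatrix(X, X, degree, offset)
  Kyy <- polyKernelMatrix(Y, Y, degree, offset)
  Kxy <- polyKernelMatrix(X, Y, degree, offset)
  within <- (sum(Kxx) - sum(diag(Kxx))) / (m * (m - 1)) +
    (sum(Kyy) - sum(diag(Kyy))) / (n * (n - 1))
  if (uStatistic) {
    if (m != n) stop("the U-statistic form needs equal sample counts")
    within - 2 * (sum(Kxy) - sum(diag(Kxy))) / (m * (m - 1))
  } else {
    within - 2 * mean(Kxy)
  }
}

#' Slice-embedding extractors
#'
#' The embedding applied to middle-depth slices before the kernel
#' distance is a pluggable contract: any function from a 2D slice
#' matrix to a numeric feature vector.  A user can supply a pretrained
#' network embedding; the package ships two deterministic baselines:
#' `rawPixelExtractor()` flattens the slice, and
#' `randomProjectionExtractor()` projects the flattened slice onto
#' `dim` fixed random directions (the projection matrix is drawn once
#' from `seed` at first use, so the embedding is a constant of the
#' configuration).
#'
#' @return an extractor function.
#' @export
rawPixelExtractor <- function() {
  function(slice) as.numeric(slice)
}

#' @rdname rawPixelExtractor
#' @param dim number of projection features (default 64).
#' @param seed seed fixing the projection matrix.
#' @export
randomProjectionExtractor <- function(dim = 64L, seed = 20240101L) {
  proj <- NULL
  function(slice) {
    x <- as.numeric(slice)
    if (is.null(proj) || nrow(proj) != length(x)) {
      proj <<- withSeed(seed,
        matrix(rnorm(length(x) * dim) / sqrt(length(x)), length(x), dim))
    }
    as.numeric(crossprod(proj, x))
  }
}

# embed the middle-depth slices of a list of volumes into a feature
# matrix (rows = volumes); slices are rescaled to [0, 1] before the
# extractor sees them so feature (and kernel) magnitudes are O(1)
# regardless of the storage range
embedSlices <- function(vols, extractor) {
  feats <- lapply(vols, function(v) {
    s <- middleSlices(v)$depth
    s <- if (v@intensityRange == RANGE_UINT8) s / 255 else (s + 1) / 2
    extractor(s)
  })
  dims <- vapply(feats, length, integer(1))
  if (length(unique(dims)) != 1L)
    stop("extractor returned inconsistent feature dimensions")
  do.call(rbind, feats)
}

#' Kernel distance between real and generated volume sets
#'
#' Extracts the middle-depth slice of every volume (rescaled to
#' \[0, 1\]), embeds it with the configured extractor, and averages the
#' unbiased polynomial-kernel MMD^2 over `nSubsets` random subsets of
#' `subsetSize` volumes per side.  The per-subset estimator is the
#' complete U-statistic (cross diagonal excluded; see
#' [mmd2Unbiased()]), and subset indices are kept sorted, so a set
#' scored against itself with subsets covering the whole sets gives
#' exactly 0.  Lower is better; unbiased estimates can be negative.
#'
#' @param reals,gens lists of [VolumeGrid-class] objects.
#' @param cfg a [KidConfig-class].
#' @param seed integer seed for the subset draws.
#' @return a list with the mean `kid` and the `perSubset` values.
#' @export
kid <- function(reals, gens, cfg = kidConfig(), seed = 1L) {
  stopifnot(is(cfg, "KidConfig"))
  ss <- min(cfg@subsetSize, length(reals), length(gens))
  if (ss < 2L) stop("need at least two volumes per set")
  X <- embedSlices(reals, cfg@extractor)
  Y <- embedSlices(gens, cfg@extractor)
  if (ncol(X) != ncol(Y))
    stop("extractor returned inconsistent feature dimensions")
  vals <- withSeed(seed,
    vapply(seq_len(cfg@nSubsets), function(i) {
      xi <- sort(sample(nrow(X), ss))
      yi <- sort(sample(nrow(Y), ss))
      mmd2Unbiased(X[xi, , drop = FALSE], Y[yi, , drop = FALSE],
                   cfg@degree, cfg@offset, uStatistic = TRUE)
    }, numeric(1)))
  list(kid = mean(vals), perSubset = vals)
}

#' @rdname kid
#' @param realRoster,genRoster rosters labelling `reals`/`gens` by
#'   class; KID is computed per class and averaged, matching how the
#'   per-checkpoint curves are recorded.
#' @return `kidPerClass()`: a list with `kid_class0`, `kid_class1` and
#'   their mean `kid_mean`.
#' @export
kidPerClass <- function(reals, gens, realRoster, genRoster,
                        cfg = kidConfig(), seed = 1L) {
  validateRoster(realRoster); validateRoster(genRoster)
  stopifnot(length(reals) == nrow(realRoster),
            length(gens) == nrow(genRoster))
  byClass <- function(cls, s)
    kid(reals[realRoster$class_label == cls],
        gens[genRoster$class_label == cls], cfg, seed = s)$kid
  k0 <- byClass(0L, seed)
  k1 <- byClass(1L, seed + 1L)
  list(kid_class0 = k0, kid_class1 = k1, kid_mean = (k0 + k1) / 2)
}

#' Per-checkpoint KID curves and snapshot selection
#'
#' A KID curve is a `data.frame` with one row per checkpoint tick:
#' strictly increasing `kimg`, per-class scores `kid_class0`,
#' `kid_class1` and their mean `kid_mean`.  `smoothKidCurve()` applies
#' a trailing moving average of `kid_mean` over `window` checkpoints
#' (truncated at the start, so early rows average what exists);
#' `selectBestSnapshot()` then returns the earliest checkpoint whose
#' smoothed value is within `tolerance` of the global smoothed minimum
#' — favouring earlier, less overfit snapshots while staying within
#' the noise band of the minimum.
#'
#' @param curve a KID-curve `data.frame` (columns `kimg`,
#'   `kid_class0`, `kid_class1`; `kid_mean` recomputed if absent).
#' @param window moving-average window in checkpoints (default 5).
#' @return `smoothKidCurve()`: the curve with a `kid_smooth` column.
#' @examples
#' curve <- data.frame(kimg = 1:5, kid_class0 = 5:1, kid_class1 = 5:1)
#' smoothKidCurve(curve)$kid_smooth[5]   # (5+4+3+2+1)/5 = 3
#' @export
smoothKidCurve <- function(curve, window = 5L) {
  curve <- validateKidCurve(curve)
  k <- curve$kid_mean
  curve$kid_smooth <- vapply(seq_along(k), function(i)
    mean(k[max(1L, i - window + 1L):i]), numeric(1))
  curve
}

#' @rdname smoothKidCurve
#' @param tolerance relative tolerance around the smoothed minimum
#'   (default 0.05).
#' @return `selectBestSnapshot()`: a list with the chosen `kimg`, its
#'   row `index` and the `smoothed` curve used.
#' @export
selectBestSnapshot <- function(curve, window = 5L, tolerance = 0.05) {
  sm <- if (!is.null(curve$kid_smooth)) curve
        else smoothKidCurve(curve, window)
  m <- min(sm$kid_smooth)
  # tolerance band on the magnitude of the minimum (unbiased KID can
  # dip below zero)
  cut <- m + tolerance * abs(m)
  idx <- which(sm$kid_smooth <= cut)[1]
  list(kimg = sm$kimg[idx], index = idx, smoothed = sm)
}

validateKidCurve <- function(curve) {
  need <- c("kimg", "kid_class0", "kid_class1")
  if (!is.data.frame(curve) || nrow(curve) == 0L)
    stop("KID curve must be a nonempty data.frame")
  if (!all(need %in% names(curve))) {
    if (!is.null(curve$kid_mean) && "kimg" %in% names(curve)) {
      curve$kid_class0 <- curve$kid_mean
      curve$kid_class1 <- curve$kid_mean
    } else stop("KID curve needs columns ", paste(need, collapse = ", "))
  }
  if (any(diff(curve$kimg) <= 0))
    stop("kimg must be strictly increasing")
  if (is.null(curve$kid_mean))
    curve$kid_mean <- (curve$kid_class0 + curve$kid_class1) / 2
  curve
}

#' @rdname smoothKidCurve
#' @param path CSV path with columns
#'   `kimg,kid_class0,kid_class1[,kid_mean]`.
#' @export
readKidCurve <- function(path) {
  validateKidCurve(utils::read.csv(path))
}

#' @rdname smoothKidCurve
#' @export
writeKidCurve <- function(curve, path) {
  curve <- validateKidCurve(curve)
  utils::write.csv(
    curve[c("kimg", "kid_class0", "kid_class1", "kid_mean")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
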