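#' @import methods
#' @importFrom stats rnorm runif rbinom sd
#' @useDynLib ada3d, .registration = TRUE
NULL

RANGE_UINT8 <- "uint8"
RANGE_MODEL <- "model"

#' VolumeGrid: a single-channel voxel cube
#'
#' The unit of data every augmentation and metric in this package
#' consumes: a grayscale scalar field on a regular (depth, height,
#' width) grid, together with its declared intensity range and voxel
#' spacing.  Two intensity conventions are supported: storage range
#' `"uint8"` (values in \[0, 255\], as CT crops are shipped) and the
#' network's symmetric `"model"` range (values in \[-1, 1\]).
#'
#' @slot voxels numeric 3D array indexed (depth, height, width).
#' @slot intensityRange `"uint8"` or `"model"`.
#' @slot spacing numeric length-3 voxel spacing in millimetres,
#'   (depth, height, width) order; defaults to 1 mm isotropic.
#'
#' @seealso [volumeGrid()], [toModelRange()], [middleSlices()]
#' @export
setClass("VolumeGrid",
  representation(
    voxels = "array",
    intensityRange = "character",
    spacing = "numeric"
  )
)

setValidity("VolumeGrid", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L)
    return("voxels must be a 3D (depth, height, width) array")
  if (any(dim(v) < 2L))
    return("each volume dimension must be at least 2")
  if (!object@intensityRange %in% c(RANGE_UINT8, RANGE_MODEL))
    return("intensityRange must be 'uint8' or 'model'")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive values")
  if (anyNA(v)) return("voxels must not contain NA")
  if (object@intensityRange == RANGE_UINT8) {
    rng <- range(v)
    if (rng[1] < 0 || rng[2] > 255)
      return("uint8 voxel values must lie in [0, 255]")
  } else if (!all(is.finite(v))) {
    # model range is nominally [-1, 1] but additive augmentations
    # (brightness, noise) legitimately exceed it, as in GAN training
    return("model-range voxels must be finite")
  }
  TRUE
})

#' Construct a VolumeGrid
#'
#' @param voxels a 3D array, or a 4D array with a singleton leading
#'   channel axis (the `(1, D, H, W)` layout used in NPZ files).
#' @param intensityRange `"uint8"` (values 0--255) or `"model"`
#'   (values -1..1).
#' @param spacing voxel spacing in mm, length 3 (recycled from length 1).
#' @return a [VolumeGrid-class] object.
#' @examples
#' v <- volumeGrid(array(0, c(8, 8, 8)))
#' extent(v)
#' @export
volumeGrid <- function(voxels, intensityRange = c("uint8", "model"),
                       spacing = c(1, 1, 1)) {
  intensityRange <- match.arg(intensityRange)
  if (length(dim(voxels)) == 4L) {
    if (dim(voxels)[1] != 1L)
      stop("4D input must have a singleton channel axis (1, D, H, W)")
    voxels <- array(voxels, dim(voxels)[-1])
  }
  if (is.null(dim(voxels)) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D or (1, D, H, W) array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(voxels) <- "double"
  new("VolumeGrid", voxels = voxels, intensityRange = intensityRange,
      spacing = as.numeric(spacing))
}

#' @describeIn volumeGrid voxel array accessor
#' @param v a VolumeGrid
#' @export
voxels <- function(v) v@voxels

#' @describeIn volumeGrid grid extent (D, H, W)
#' @export
extent <- function(v) dim(v@voxels)

#' @describeIn volumeGrid declared intensity range (`"uint8"`/`"model"`)
#' @export
intensityRange <- function(v) v@intensityRange

#' @describeIn volumeGrid voxel spacing in mm
#' @export
spacingMm <- function(v) v@spacing

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeGrid %d x %d x %d [%s range], spacing %s mm\n",
              d[1], d[2], d[3], object@intensityRange,
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  intensity: min %.4g, max %.4g, mean %.4g\n",
              min(object@voxels), max(object@voxels),
              mean(object@voxels)))
})

# replace voxels, keeping metadata; validity re-checked
replaceVoxels <- function(v, arr, intensityRange = v@intensityRange) {
  new("VolumeGrid", voxels = arr, intensityRange = intensityRange,
      spacing = v@spacing)
}

#' SSIM hyperparameters
#'
#' Gaussian-window structural-similarity settings: a cubic window of
#' odd size (default 11 x 11 x 11) with per-axis standard deviation
#' sigma (default 1.5), dynamic range L (default 1) and the standard
#' stability constants C1 = (0.01 L)^2, C2 = (0.03 L)^2.
#'
#' @slot windowSize odd integer edge length of the cubic window.
#' @slot sigma Gaussian standard deviation per axis.
#' @slot L dynamic range of the (rescaled) input intensities.
#' @slot C1,C2 stability constants.
#' @export
setClass("SsimParams",
  representation(windowSize = "integer", sigma = "numeric",
                 L = "numeric", C1 = "numeric", C2 = "numeric")
)

setValidity("SsimParams", function(object) {
  if (object@windowSize < 1L || object@windowSize %% 2L == 0L)
    return("windowSize must be odd and positive")
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@C1 <= 0 || object@C2 <= 0) return("C1 and C2 must be > 0")
  TRUE
})

#' @param windowSize odd cubic window edge (default 11).
#' @param sigma Gaussian std per axis (default 1.5).
#' @param L dynamic range (default 1).
#' @param k1,k2 constants entering C1 = (k1 L)^2, C2 = (k2 L)^2.
#' @return an [SsimParams-class] object.
#' @rdname SsimParams-class
#' @export
ssimParams <- function(windowSize = 11L, sigma = 1.5, L = 1,
                       k1 = 0.01, k2 = 0.03) {
  new("SsimParams", windowSize = as.integer(windowSize), sigma = sigma,
      L = L, C1 = (k1 * L)^2, C2 = (k2 * L)^2)
}

setMethod("show", "SsimParams", function(object) {
  cat(sprintf("SsimParams: window %d^3, sigma %.3g, L %.3g, C1 %.3g, C2 %.3g\n",
              object@windowSize, object@sigma, object@L,
              object@C1, object@C2))
})

#' KID configuration
#'
#' Settings for the kernel distance between real and generated volume
#' sets: a polynomial kernel (x.y/d + 1)^degree on embedded
#' middle-depth slices, estimated by unbiased squared MMD averaged over
#' random subsets.
#'
#' @slot degree polynomial kernel degree (default 3).
#' @slot offset kernel offset (default 1).
#' @slot subsetSize number of samples per subset.
#' @slot nSubsets number of random subsets averaged.
#' @slot extractor a function mapping a 2D slice matrix to a numeric
#'   feature vector (the embedding contract; a pretrained network can be
#'   plugged in here).
#' @export
setClass("KidConfig",
  representation(degree = "numeric", offset = "numeric",
                 subsetSize = "integer", nSubsets = "integer",
                 extractor = "function")
)

setValidity("KidConfig", function(object) {
  if (object@subsetSize < 2L) return("subsetSize must be >= 2")
  if (object@nSubsets < 1L) return("nSubsets must be >= 1")
  TRUE
})

#' @param degree,offset polynomial kernel parameters.
#' @param subsetSize samples per subset (default 50).
#' @param nSubsets subsets averaged (default 10).
#' @param extractor slice-embedding function; defaults to a
#'   deterministic random-projection embedding of raw pixels
#'   ([randomProjectionExtractor()]).
#' @return a [KidConfig-class] object.
#' @rdname KidConfig-class
#' @export
kidConfig <- function(degree = 3, offset = 1, subsetSize = 50L,
                      nSubsets = 10L,
                      extractor = randomProjectionExtractor()) {
  new("KidConfig", degree = degree, offset = offset,
      subsetSize = as.integer(subsetSize),
      nSubsets = as.integer(nSubsets), extractor = extractor)
}

setMethod("show", "KidConfig", function(object) {
  cat(sprintf(
    "KidConfig: poly kernel degree %g offset %g, %d subsets of %d\n",
    object@degree, object@offset, object@nSubsets, object@subsetSize))
})
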