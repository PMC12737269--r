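#' Read a voxel volume from NPZ or NIfTI
#'
#' NPZ files must carry the volume under key `"voxels"` as a `(D, H, W)`
#' or `(1, D, H, W)` array (an optional `"label"` member is ignored
#' here).  NIfTI volumes are read in voxel order, ignoring orientation
#' matrices; spacing is taken from the header when present, else 1 mm
#' isotropic.  The intensity range is inferred from the stored dtype:
#' unsigned bytes give `"uint8"`, floating point data within \[-1, 1\]
#' give `"model"`, other floating data within \[0, 255\] give
#' `"uint8"`.
#'
#' @param path file path (`.npz`, `.nii` or `.nii.gz`).
#' @param format `"npz"` or `"nifti"`; guessed from the extension by
#'   default.
#' @return a [VolumeGrid-class].
#' @seealso [saveVolume()]
#' @export
loadVolume <- function(path, format = c("auto", "npz", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.npz$", path)) "npz"
              else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
              else stop("cannot infer format from extension: ", path)
  }
  if (format == "npz") {
    members <- zipReadMembers(path)
    if (!"voxels.npy" %in% names(members))
      stop("NPZ file lacks a 'voxels' member: ", path)
    arr <- npyParse(members[["voxels.npy"]])
    descr <- attr(arr, "npyDescr")
    attr(arr, "npyDescr") <- NULL
    if (!length(dim(arr)) %in% c(3L, 4L))
      stop("volume array must have rank 3 or 4, got rank ",
           length(dim(arr)))
    rng <- inferRange(arr, descr)
    volumeGrid(arr, intensityRange = rng)
  } else {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim(img))
    if (!length(dim(arr)) %in% c(3L, 4L))
      stop("NIfTI volume must have rank 3 or 4, got rank ",
           length(dim(arr)))
    if (length(dim(arr)) == 4L) {
      if (!1L %in% dim(arr)) stop("multi-channel NIfTI not supported")
      arr <- array(arr, dim(arr)[dim(arr) > 1L])
    }
    pd <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
    if (any(!is.finite(pd)) || any(pd <= 0)) pd <- c(1, 1, 1)
    storage.mode(arr) <- "double"
    volumeGrid(arr, intensityRange = inferRange(arr, ""),
               spacing = pd)
  }
}

inferRange <- function(arr, descr) {
  if (identical(descr, "|u1")) return("uint8")
  rng <- range(arr)
  if (rng[1] >= -1 - 1e-9 && rng[2] <= 1 + 1e-9 && rng[1] < 0) "model"
  else if (rng[1] >= 0 && rng[2] <= 255) "uint8"
  else stop("cannot infer intensity range: values in [",
            rng[1], ", ", rng[2], "]")
}

#' Write a voxel volume to NPZ or NIfTI
#'
#' The round trip `loadVolume(saveVolume(v))` is voxelwise exact:
#' uint8-range volumes with integral values are stored as unsigned
#' bytes, anything else as 64-bit floats.
#'
#' @param v a [VolumeGrid-class].
#' @param path destination path.
#' @param format `"npz"` or `"nifti"`; guessed from the extension.
#' @param label optional integer class label stored alongside the NPZ
#'   voxels.
#' @return `path`, invisibly.
#' @export
saveVolume <- function(v, path, format = c("auto", "npz", "nifti"),
                       label = NULL) {
  stopifnot(is(v, "VolumeGrid"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.npz$", path)) "npz"
              else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
              else stop("cannot infer format from extension: ", path)
  }
  arr <- v@voxels
  asBytes <- v@intensityRange == RANGE_UINT8 &&
    max(abs(arr - round(arr))) < 1e-9
  if (format == "npz") {
    members <- list("voxels.npy" = npySerialize(arr, uint8 = asBytes))
    if (!is.null(label))
      members[["label.npy"]] <- npySerialize(as.numeric(label))
    zipWrite(path, members)
  } else {
    if (asBytes) storage.mode(arr) <- "integer"
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- v@spacing
    RNifti::writeNifti(img, path,
                       datatype = if (asBytes) "uint8" else "double")
  }
  invisible(path)
}

#' Map intensities between storage and model range
#'
#' `toModelRange()` applies the affine map `x / 127.5 - 1`, taking
#' uint8 storage values 0--255 onto the symmetric \[-1, 1\] range the
#' generator and discriminator operate in; `fromModelRange()` inverts
#' it (values are clamped to \[0, 255\] and NOT rounded, so the round
#' trip is exact to within float precision).
#'
#' @param v a [VolumeGrid-class].
#' @return a [VolumeGrid-class] in the other range.
#' @examples
#' v <- volumeGrid(array(255, c(4, 4, 4)))
#' range(voxels(toModelRange(v)))   # 1 1
#' @export
toModelRange <- function(v) {
  stopifnot(is(v, "VolumeGrid"))
  if (v@intensityRange == RANGE_MODEL) {
    warning("volume already in model range; returning unchanged")
    return(v)
  }
  replaceVoxels(v, v@voxels / 127.5 - 1, RANGE_MODEL)
}

#' @rdname toModelRange
#' @export
fromModelRange <- function(v) {
  stopifnot(is(v, "VolumeGrid"))
  if (v@intensityRange == RANGE_UINT8) {
    warning("volume already in uint8 range; returning unchanged")
    return(v)
  }
  replaceVoxels(v, pmin(pmax((v@voxels + 1) * 127.5, 0), 255),
                RANGE_UINT8)
}

#' Extract the middle slice along each principal axis
#'
#' Returns the three orthogonal central slices (index `floor(n/2)`,
#' zero-based, along each axis — i.e. slice 16 of a 32-voxel axis).
#' The depth slice is the one the kernel-distance metric embeds.
#'
#' @param v a [VolumeGrid-class].
#' @return a list with matrices `depth` (H x W), `height` (D x W) and
#'   `width` (D x H).
#' @export
middleSlices <- function(v) {
  stopifnot(is(v, "VolumeGrid"))
  d <- dim(v@voxels)
  i <- d %/% 2L + 1L  # floor(n/2) zero-based -> 1-based
  list(depth = v@voxels[i[1], , ],
       height = v@voxels[, i[2], ],
       width = v@voxels[, , i[3]])
}

# trilinear (separable) resampling of a 3D array to a target extent,
# align-corners-off: output centre i+0.5 maps to input (i+0.5)*n_in/n_out
resampleTrilinear <- function(arr, target) {
  for (ax in 1:3) {
    nIn <- dim(arr)[ax]; nOut <- target[ax]
    if (nIn == nOut) next
    pos <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5  # continuous 1-based
    i0 <- floor(pos); w <- pos - i0
    i0c <- pmin(pmax(i0, 1L), nIn); i1c <- pmin(pmax(i0 + 1L, 1L), nIn)
    arr <- aperm(arr, c(ax, setdiff(1:3, ax)))
    m <- matrix(arr, dim(arr)[1], prod(dim(arr)[-1]))
    out <- m[i0c, , drop = FALSE] * (1 - w) + m[i1c, , drop = FALSE] * w
    dim(out) <- c(nOut, dim(arr)[-1])
    arr <- aperm(out, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

#' Resample a volume through a chain of cubic extents
#'
#' Sequential trilinear resampling through a list of target edge
#' lengths.  The default chain reproduces the preprocessing applied to
#' lung-nodule CT crops: an 80-voxel cube is downsampled to 28, blown
#' up to 64, and finally reduced to the 32-voxel training size.  Pass
#' `centerCrop` to cut a centred cube first (e.g. 80 from a larger
#' scan).
#'
#' @param v a cubic [VolumeGrid-class].
#' @param stages integer vector of successive cubic target extents.
#' @param centerCrop optional edge length of a centred pre-crop.
#' @return a [VolumeGrid-class] with extent `rep(tail(stages, 1), 3)`.
#' @export
resampleChain <- function(v, stages = c(28L, 64L, 32L),
                          centerCrop = NULL) {
  stopifnot(is(v, "VolumeGrid"))
  d <- dim(v@voxels)
  if (length(unique(d)) != 1L) stop("resampleChain expects a cubic volume")
  if (length(stages) == 0L) stop("stages must be nonempty")
  if (any(stages <= 0)) stop("target extents must be positive")
  arr <- v@voxels
  if (!is.null(centerCrop)) {
    if (centerCrop > d[1]) stop("centerCrop larger than the volume")
    lo <- (d[1] - centerCrop) %/% 2L
    idx <- (lo + 1L):(lo + centerCrop)
    arr <- arr[idx, idx, idx]
  }
  for (s in stages) arr <- resampleTrilinear(arr, rep(as.integer(s), 3L))
  if (v@intensityRange == RANGE_MODEL) arr <- pmin(pmax(arr, -1), 1)
  replaceVoxels(v, arr)
}

#' Rosters of labelled volumes
#'
#' A roster is a plain `data.frame` with character column `volume_id`
#' (unique) and integer column `class_label` (0 = benign-leaning,
#' 1 = malignant-leaning nodules).  `makeRoster()` builds one with
#' generated ids; `readRoster()`/`writeRoster()` exchange the CSV form.
#'
#' @param nClass0,nClass1 number of entries per class.
#' @param prefix id prefix.
#' @return a roster `data.frame`.
#' @export
makeRoster <- function(nClass0, nClass1, prefix = "vol") {
  stopifnot(nClass0 >= 0, nClass1 >= 0)
  n <- nClass0 + nClass1
  data.frame(
    volume_id = sprintf("%s%05d", prefix, seq_len(n)),
    class_label = rep(c(0L, 1L), c(nClass0, nClass1)),
    stringsAsFactors = FALSE
  )
}

validateRoster <- function(r) {
  if (!is.data.frame(r) ||
      !all(c("volume_id", "class_label") %in% names(r)))
    stop("a roster needs columns volume_id and class_label")
  if (anyDuplicated(r$volume_id)) stop("volume_ids must be unique")
  if (!all(r$class_label %in% c(0L, 1L)))
    stop("class_label must be 0 or 1")
  invisible(r)
}

#' @rdname makeRoster
#' @param path CSV path with columns `volume_id,class_label`.
#' @export
readRoster <- function(path) {
  r <- utils::read.csv(path, colClasses = c(volume_id = "character"))
  r$class_label <- as.integer(r$class_label)
  validateRoster(r)
  r
}

#' @rdname makeRoster
#' @param roster a roster `data.frame`.
#' @export
writeRoster <- function(roster, path) {
  validateRoster(roster)
  utils::write.csv(roster[c("volume_id", "class_label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Balance a two-class roster by random majority downsampling
#'
#' Removes uniformly random majority-class entries until both classes
#' hold the minority count, reproducibly under `seed`.  Applied to the
#' lung-nodule training split (863 benign-leaning vs 295
#' malignant-leaning volumes) this removes 568 entries and leaves 295
#' per class — balancing the set and, deliberately, shrinking it to
#' stress the limited-data regime.
#'
#' @param roster a roster `data.frame` containing both classes.
#' @param seed integer RNG seed controlling the removal set.
#' @return a list with elements `roster` (the balanced roster, input
#'   order preserved), `removed` (the removed rows) and `removedCount`.
#' @examples
#' b <- balanceRoster(makeRoster(863, 295), seed = 1)
#' b$removedCount          # 568
#' table(b$roster$class_label)
#' @export
balanceRoster <- function(roster, seed) {
  validateRoster(roster)
  counts <- table(factor(roster$class_label, levels = c(0L, 1L)))
  if (any(counts == 0L))
    stop("both classes must be present to balance")
  minority <- min(counts)
  majClass <- as.integer(names(counts)[which.max(counts)])
  excess <- max(counts) - minority
  if (excess == 0L)
    return(list(roster = roster, removed = roster[0, ],
                removedCount = 0L))
  majIdx <- which(roster$class_label == majClass)
  rng <- localRng(seed)
  drop <- sort(sample(majIdx, excess))
  restoreRng(rng)
  list(roster = roster[-drop, , drop = FALSE],
       removed = roster[drop, , drop = FALSE],
       removedCount = excess)
}

# run code under a private RNG stream without disturbing the caller's
localRng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restoreRng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
withSeed <- function(seed, expr) {
  old <- localRng(seed)
  on.exit(restoreRng(old))
  expr
}
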