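#' Separable 3D Gaussian window
#'
#' The cubic Gaussian weighting window used by the volumetric
#' structural-similarity score: outer product of three identical 1D
#' discrete Gaussians, normalized to sum 1.
#'
#' @param params an [SsimParams-class].
#' @return a `windowSize^3` array summing to 1.
#' @export
gaussianWindow <- function(params = ssimParams()) {
  stopifnot(is(params, "SsimParams"))
  g <- gaussian1d(params@windowSize, params@sigma)
  w <- outer(outer(g, g), g)
  w / sum(w)
}

gaussian1d <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# separable "valid" correlation of a 3D array with a 1D kernel applied
# along every axis
convValid3 <- function(arr, g) {
  win <- length(g)
  for (ax in 1:3) {
    nIn <- dim(arr)[ax]
    nOut <- nIn - win + 1L
    if (nOut < 1L) stop("volume smaller than the window")
    W <- matrix(0, nOut, nIn)
    for (i in seq_len(nOut)) W[i, i:(i + win - 1L)] <- g
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    out <- W %*% matrix(a, da[1], prod(da[-1]))
    arr <- aperm(array(out, c(nOut, da[2], da[3])), order(perm))
  }
  arr
}

# map intensities to [0, L] for scoring
ssimScale <- function(v, L) {
  if (v@intensityRange == RANGE_UINT8) v@voxels / 255 * L
  else (v@voxels + 1) / 2 * L
}

#' Volumetric structural similarity (3D SSIM)
#'
#' Local luminance/contrast/structure similarity computed over 3D
#' neighbourhoods: local means, variances and covariance are estimated
#' by convolution with the cubic Gaussian window (11^3, sigma 1.5 by
#' default), combined voxelwise by the standard SSIM formula with
#' stability constants C1 = (0.01 L)^2, C2 = (0.03 L)^2, and averaged
#' over the valid region to one scalar in \[-1, 1\].  Inputs are
#' rescaled to \[0, L\] (uint8 via /255, model range via (x+1)/2)
#' before scoring.
#'
#' @param a,b [VolumeGrid-class] objects of equal extent.
#' @param params an [SsimParams-class].
#' @return mean SSIM scalar.
#' @examples
#' v <- volumeGrid(array(runif(16^3, 0, 255), c(16, 16, 16)))
#' ssim3d(v, v)   # 1
#' @export
ssim3d <- function(a, b, params = ssimParams()) {
  stopifnot(is(a, "VolumeGrid"), is(b, "VolumeGrid"),
            is(params, "SsimParams"))
  if (!identical(dim(a@voxels), dim(b@voxels)))
    stop("volumes must share one extent")
  x <- ssimScale(a, params@L)
  y <- ssimScale(b, params@L)
  g <- gaussian1d(params@windowSize, params@sigma)
  mux <- convValid3(x, g)
  muy <- convValid3(y, g)
  sxx <- convValid3(x * x, g) - mux^2
  syy <- convValid3(y * y, g) - muy^2
  sxy <- convValid3(x * y, g) - mux * muy
  C1 <- params@C1; C2 <- params@C2
  ssimMap <- ((2 * mux * muy + C1) * (2 * sxy + C2)) /
    ((mux^2 + muy^2 + C1) * (sxx + syy + C2))
  mean(ssimMap)
}

#' Pairwise SSIM distributions of real and generated sets
#'
#' Scores every unordered pair of real volumes and every real x
#' generated pair, bins both score sets into shared-edge histograms,
#' and reports their overlap coefficient (the shared area of the two
#' density-normalized histograms; 1 = identical distributions).  A
#' larger overlap means the generated volumes resemble the reals as
#' much as the reals resemble each other.
#'
#' @param reals list of at least two [VolumeGrid-class] objects.
#' @param gens nonempty list of [VolumeGrid-class] objects.
#' @param params an [SsimParams-class].
#' @param nBins number of shared histogram bins.
#' @return a list with `realReal` and `realGen` score vectors,
#'   a `histogram` data.frame (`bin_left`, `bin_right`,
#'   `count_real_real`, `count_real_gen`) and the `overlap`
#'   coefficient.
#' @export
ssimPairDistributions <- function(reals, gens, params = ssimParams(),
                                  nBins = 30L) {
  if (length(reals) < 2L)
    stop("need at least two real volumes for real-real pairs")
  if (length(gens) < 1L) stop("need at least one generated volume")
  nR <- length(reals)
  rr <- unlist(lapply(seq_len(nR - 1L), function(i)
    vapply((i + 1L):nR, function(j)
      ssim3d(reals[[i]], reals[[j]], params), numeric(1))))
  rg <- as.vector(vapply(gens, function(gvol)
    vapply(reals, function(rvol) ssim3d(rvol, gvol, params), numeric(1)),
    numeric(nR)))
  lim <- range(c(rr, rg))
  if (diff(lim) == 0) lim <- lim + c(-1e-6, 1e-6)
  edges <- seq(lim[1], lim[2], length.out = nBins + 1L)
  hr <- graphics::hist(rr, breaks = edges, plot = FALSE)$counts
  hg <- graphics::hist(rg, breaks = edges, plot = FALSE)$counts
  overlap <- sum(pmin(hr / sum(hr), hg / sum(hg)))
  list(realReal = rr, realGen = rg,
       histogram = data.frame(bin_left = edges[-length(edges)],
                              bin_right = edges[-1],
                              count_real_real = hr,
                              count_real_gen = hg),
       overlap = overlap)
}
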