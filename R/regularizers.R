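# Depth-aware GAN regularizers, defined as pure functionals over a
# differentiable-network contract so they are testable with closed-form
# toy networks; wiring into a training loop is the caller's job.

#' Differentiable-network contracts
#'
#' The regularizers do not know about any particular network; they
#' consume plain-list contracts exposing exact gradients.
#'
#' A *discriminator contract* is `list(f, grad)` where `f(x)` maps a
#' voxel array to a scalar and `grad(x)` returns the exact gradient of
#' `f` with respect to every voxel (same shape as `x`).
#'
#' A *generator contract* is `list(f, vjp)` where `f(z)` maps a latent
#' vector to a voxel array and `vjp(z, y)` returns the exact gradient
#' of the inner product `<f(z), y>` with respect to `z` (a
#' vector-Jacobian product).
#'
#' `linearDiscriminator(w)` builds the toy `D(x) = sum(w * x)`;
#' `quadraticDiscriminator(a)` builds `D(x) = sum(a * x^2) / 2`;
#' `scaledOnesGenerator(extent)` builds `G(z) = z[1] * ones(extent)`;
#' `linearGenerator(W)` builds the voxelwise-linear `G(z) = W z`
#' reshaped to `extent` (rows of `W` indexed by voxel).
#'
#' @param w array (or scalar, recycled) of linear weights.
#' @return a contract list.
#' @export
linearDiscriminator <- function(w) {
  force(w)
  list(f = function(x) sum(w * x),
       grad = function(x) array(w * array(1, dim(x)), dim(x)))
}

#' @rdname linearDiscriminator
#' @param a array (or scalar) of quadratic coefficients.
#' @export
quadraticDiscriminator <- function(a) {
  force(a)
  list(f = function(x) sum(a * x^2) / 2,
       grad = function(x) a * x)
}

#' @rdname linearDiscriminator
#' @param extent output extent (D, H, W).
#' @export
scaledOnesGenerator <- function(extent) {
  force(extent)
  list(f = function(z) array(z[1], extent),
       vjp = function(z, y) c(sum(y), rep(0, length(z) - 1)))
}

#' @rdname linearDiscriminator
#' @param W matrix with `prod(extent)` rows and latent-dimension
#'   columns.
#' @param extent output extent (D, H, W).
#' @export
linearGenerator <- function(W, extent) {
  force(W); force(extent)
  stopifnot(nrow(W) == prod(extent))
  list(f = function(z) array(W %*% z, extent),
       vjp = function(z, y) as.numeric(crossprod(W, as.vector(y))))
}

#' R1 gradient penalty with the depth dimension
#'
#' The zero-centred gradient penalty on real samples, summing squared
#' discriminator input-gradients over channel, depth, height and width
#' — the volumetric extension of the planar penalty, where depth enters
#' the sum like any spatial axis:
#' `(gamma / 2) * mean_batch sum_{c,d,h,w} (dD/dx)^2`.
#'
#' @param d a discriminator contract (see [linearDiscriminator()]).
#' @param reals list of model-range [VolumeGrid-class] objects (or
#'   plain arrays).
#' @param gamma non-negative penalty weight (0.6 in the final training
#'   configuration, selected from the sweep 10, 5, 1, 0.8, 0.6).
#' @return the scalar penalty.
#' @examples
#' d <- linearDiscriminator(1)
#' v <- volumeGrid(array(0, c(4, 4, 4)), "model")
#' r1Penalty(d, list(v), gamma = 0.6)   # 0.3 * 64 = 19.2
#' @export
r1Penalty <- function(d, reals, gamma) {
  stopifnot(is.list(d), is.function(d$grad))
  if (gamma < 0) stop("gamma must be >= 0")
  arrs <- lapply(reals, function(v)
    if (is(v, "VolumeGrid")) v@voxels else v)
  sq <- vapply(arrs, function(x) sum(d$grad(x)^2), numeric(1))
  (gamma / 2) * mean(sq)
}

#' Path-length regularization normalized by the voxel count
#'
#' Keeps the generator's latent-to-volume Jacobian norm close to its
#' running mean.  Per sample, unit Gaussian noise `y` over the output
#' voxels is scaled by `1 / sqrt(D * H * W)` — the volumetric
#' normalization, replacing the planar `1 / sqrt(H * W)` — and the
#' path length is `|| grad_z <G(z), y> ||`.  The penalty is the mean
#' squared deviation of the lengths from the running mean, which is
#' then updated by EMA.
#'
#' @param g a generator contract (see [scaledOnesGenerator()]).
#' @param latents matrix of latent vectors, one row per sample.
#' @param plMean running mean of path lengths (start at 0).
#' @param extent output extent (D, H, W); must match `g`'s output.
#' @param plDecay EMA weight for the running-mean update (default
#'   0.01).
#' @param noise optional array of unscaled unit noise, dim
#'   `c(nrow(latents), extent)`, for deterministic use; drawn from the
#'   current RNG stream when NULL.
#' @return `list(penalty, plMean, lengths)` with the updated running
#'   mean.
#' @export
pathLengthPenalty <- function(g, latents, plMean, extent,
                              plDecay = 0.01, noise = NULL) {
  stopifnot(is.list(g), is.function(g$vjp), is.matrix(latents))
  nvox <- prod(extent)
  n <- nrow(latents)
  out0 <- g$f(latents[1, ])
  if (length(dim(out0)) != length(extent) ||
      !all(dim(out0) == extent))
    stop("generator output extent does not match 'extent'")
  if (is.null(noise))
    noise <- array(rnorm(n * nvox), c(n, extent))
  lengths <- vapply(seq_len(n), function(i) {
    y <- array(noise[i, , , ], extent) / sqrt(nvox)
    sqrt(sum(g$vjp(latents[i, ], y)^2))
  }, numeric(1))
  penalty <- mean((lengths - plMean)^2)
  plMean <- plMean + plDecay * (mean(lengths) - plMean)
  list(penalty = penalty, plMean = plMean, lengths = lengths)
}

#' Regularizer configuration
#'
#' Carries the penalty weights and the lazy-evaluation intervals (R1
#' every 16 minibatches, path length every 4); enforcement of the
#' intervals is the training loop's job.
#'
#' @param r1Gamma R1 weight (default 0.6, the final training value).
#' @param plDecay path-length EMA decay (default 0.01).
#' @param r1Interval,plInterval lazy intervals in minibatches.
#' @return a `RegularizerConfig` list.
#' @export
regularizerConfig <- function(r1Gamma = 0.6, plDecay = 0.01,
                              r1Interval = 16L, plInterval = 4L) {
  stopifnot(r1Gamma >= 0, plDecay > 0, plDecay <= 1)
  structure(list(r1Gamma = r1Gamma, plDecay = plDecay,
                 r1Interval = as.integer(r1Interval),
                 plInterval = as.integer(plInterval)),
            class = "RegularizerConfig")
}
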