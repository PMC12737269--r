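#' Adaptive augmentation controller state
#'
#' The controller watches the fraction of real samples the
#' discriminator scores positive (an overfitting heuristic, tracked as
#' an exponential moving average `rHat`) and nudges the shared
#' augmentation probability `p` towards the point where that fraction
#' equals `target`: too many positives means the discriminator is
#' getting overconfident on reals, so augmentation is strengthened;
#' too few, and it is relaxed.
#'
#' @slot p augmentation probability in \[0, 1\].
#' @slot rHat running positive-rate estimate (NA before the first
#'   batch).
#' @slot imagesSeen non-negative count of real images accumulated.
#' @slot target positive-rate setpoint (default 0.7).
#' @slot speedKimg adjustment speed: `p` traverses the full \[0, 1\]
#'   range in `speedKimg` thousand images (default 500).
#' @slot emaLambda per-batch EMA weight for `rHat` (default 16/4000, so
#'   roughly one checkpoint tick of batches dominates).
#' @slot signConvention if TRUE the heuristic is `E[sign(logit)]`
#'   compared on the \[-1, 1\] scale (the convention of the original 2D
#'   controller) instead of the positive fraction on \[0, 1\].
#' @export
setClass("AdaState",
  representation(p = "numeric", rHat = "numeric",
                 imagesSeen = "numeric", target = "numeric",
                 speedKimg = "numeric", emaLambda = "numeric",
                 signConvention = "logical")
)

setValidity("AdaState", function(object) {
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  if (object@imagesSeen < 0) return("imagesSeen must be >= 0")
  if (object@speedKimg <= 0) return("speedKimg must be > 0")
  if (object@emaLambda <= 0 || object@emaLambda > 1)
    return("emaLambda must be in (0, 1]")
  TRUE
})

#' @param p initial augmentation probability.
#' @param target positive-rate setpoint.
#' @param speedKimg adjustment speed in thousand images.
#' @param emaLambda per-batch EMA weight.
#' @param signConvention use the E\[sign\] heuristic instead of the
#'   positive fraction.
#' @return an [AdaState-class].
#' @rdname AdaState-class
#' @export
adaState <- function(p = 0, target = 0.7, speedKimg = 500,
                     emaLambda = 16 / 4000, signConvention = FALSE) {
  new("AdaState", p = p, rHat = NA_real_, imagesSeen = 0,
      target = target, speedKimg = speedKimg, emaLambda = emaLambda,
      signConvention = signConvention)
}

setMethod("show", "AdaState", function(object) {
  cat(sprintf(
    "AdaState: p %.4f, rHat %s, %.0f images seen (target %.2f, speed %g kimg)\n",
    object@p, ifelse(is.na(object@rHat), "-", sprintf("%.3f", object@rHat)),
    object@imagesSeen, object@target, object@speedKimg))
})

#' Accumulate a batch of real-sample discriminator logits
#'
#' Updates the running positive-rate estimate with the fraction of
#' strictly positive logits in the batch (zeros count as negative) and
#' advances the images-seen counter.  The first batch initialises the
#' estimate directly; later batches blend in with weight `emaLambda`.
#'
#' @param state an [AdaState-class].
#' @param realLogits nonempty numeric vector of discriminator outputs
#'   on real samples.
#' @return the updated [AdaState-class].
#' @export
accumulate <- function(state, realLogits) {
  stopifnot(is(state, "AdaState"))
  if (length(realLogits) == 0L)
    stop("realLogits must be nonempty")
  stat <- if (state@signConvention) mean(sign(realLogits))
          else mean(realLogits > 0)
  state@rHat <- if (is.na(state@rHat)) stat
                else (1 - state@emaLambda) * state@rHat +
                     state@emaLambda * stat
  state@imagesSeen <- state@imagesSeen + length(realLogits)
  state
}

#' Adjust the augmentation probability
#'
#' Moves `p` by `nImages / (speedKimg * 1000)` in the direction of the
#' sign of `rHat - target`, clamped to \[0, 1\].  With the defaults
#' each 4000-image tick can move `p` by at most 0.008.
#'
#' @param state an [AdaState-class] with a non-NA `rHat`.
#' @param nImages number of images this adjustment accounts for.
#' @return the updated [AdaState-class].
#' @examples
#' s <- adaState(p = 0.5)
#' s@rHat <- 1
#' adjustP(s, 4000)@p   # 0.508
#' @export
adjustP <- function(state, nImages) {
  stopifnot(is(state, "AdaState"), nImages > 0)
  if (is.na(state@rHat)) return(state)
  step <- sign(state@rHat - state@target) * nImages /
    (state@speedKimg * 1000)
  state@p <- min(max(state@p + step, 0), 1)
  state
}

#' Training schedule
#'
#' The bookkeeping of a training run: batch size 16, 300 kimg total
#' (300,000 real images shown to the discriminator) and a checkpoint
#' tick every ~4000 images, at which metric curves are recorded — 75
#' ticks over the full schedule.  Optimizer metadata (Adam, lr 0.002,
#' beta1 0.9, beta2 0.999) is carried for config completeness.
#'
#' @param batchSize images per discriminator batch.
#' @param totalKimg schedule length in thousand images.
#' @param imagesPerTick checkpoint interval in images.
#' @param lr,beta1,beta2 optimizer metadata.
#' @return a `TrainSchedule` list with the fields above plus
#'   `totalImages`.
#' @export
trainSchedule <- function(batchSize = 16L, totalKimg = 300,
                          imagesPerTick = 4000L, lr = 0.002,
                          beta1 = 0.9, beta2 = 0.999) {
  stopifnot(batchSize > 0, totalKimg > 0, imagesPerTick > 0)
  structure(list(batchSize = as.integer(batchSize),
                 totalKimg = totalKimg,
                 totalImages = totalKimg * 1000,
                 imagesPerTick = as.integer(imagesPerTick),
                 lr = lr, beta1 = beta1, beta2 = beta2),
            class = "TrainSchedule")
}

#' @rdname trainSchedule
#' @param schedule a `TrainSchedule`.
#' @return `tickBoundaries()`: the images-seen values of every
#'   checkpoint tick.
#' @export
tickBoundaries <- function(schedule) {
  seq(schedule$imagesPerTick, schedule$totalImages,
      by = schedule$imagesPerTick)
}

#' Simulate the controller against a discriminator-response model
#'
#' Drives [accumulate()]/[adjustP()] batch by batch through a full
#' schedule against a response model `sim(p)` giving the expected
#' fraction of reals scored positive at augmentation strength `p`
#' (monotone decreasing for a sensible discriminator: stronger
#' augmentation makes reals harder to recognise).  Per batch, the
#' positive count is drawn Binomial(batchSize, sim(p)).  For a
#' monotone model crossing the target, `p` settles in a neighbourhood
#' of the crossing point.
#'
#' @param sim function mapping p to an expected positive fraction.
#' @param schedule a [trainSchedule()].
#' @param state0 initial [AdaState-class].
#' @param seed integer seed for the binomial draws.
#' @return a `data.frame` trajectory with columns `images_seen`, `p`,
#'   `r_hat`, one row per batch, plus the final state as
#'   `attr(, "state")`.
#' @export
runController <- function(sim, schedule = trainSchedule(),
                          state0 = adaState(), seed = 1L) {
  stopifnot(is.function(sim), is(state0, "AdaState"))
  nBatches <- floor(schedule$totalImages / schedule$batchSize)
  bs <- schedule$batchSize
  # plain locals in the loop; S4 slot assignment is too slow for 18k+
  # iterations
  p <- state0@p; rHat <- state0@rHat
  imagesSeen <- state0@imagesSeen
  target <- state0@target
  stepUnit <- bs / (state0@speedKimg * 1000)
  lam <- state0@emaLambda
  signConv <- state0@signConvention
  pTr <- numeric(nBatches); rTr <- numeric(nBatches)
  withSeed(seed, {
    for (i in seq_len(nBatches)) {
      frac <- sim(p)
      k <- rbinom(1, bs, min(max(frac, 0), 1))
      stat <- if (signConv) (2 * k - bs) / bs else k / bs
      rHat <- if (is.na(rHat)) stat else (1 - lam) * rHat + lam * stat
      imagesSeen <- imagesSeen + bs
      p <- min(max(p + sign(rHat - target) * stepUnit, 0), 1)
      pTr[i] <- p; rTr[i] <- rHat
    }
  })
  state <- state0
  state@p <- p; state@rHat <- rHat; state@imagesSeen <- imagesSeen
  traj <- data.frame(images_seen = seq_len(nBatches) * bs,
                     p = pTr, r_hat = rTr)
  attr(traj, "state") <- state
  traj
}

#' Named discriminator response models for controller simulations
#'
#' Each entry maps the augmentation probability `p` to the expected
#' fraction of real samples receiving a positive discriminator logit.
#' `const1` and `const0` drive the controller to its bounds; `linear`
#' (`r(p) = 1 - p`) has its fixed point where `1 - p` equals the
#' controller target.
#'
#' @format A named list of functions of `p`.
#' @seealso [runController()]
#' @export
responseModels <- list(
  const1 = function(p) 1,
  const0 = function(p) 0,
  linear = function(p) 1 - p
)
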