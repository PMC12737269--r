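#' Augmentation pipeline configuration
#'
#' Per-category enable flags and per-transform strength parameters for
#' the volumetric augmentation pipeline.  The five categories mirror
#' the training-time pipeline: pixel-level edits (sagittal flips, 90
#' degree axial rotations, integer translations), geometric warps
#' (isotropic/anisotropic scaling, arbitrary rotations, fractional
#' translations), colour transforms (brightness, contrast, luma
#' inversion, hue rotation, saturation — the last two exact no-ops on
#' single-channel data, kept so the pipeline shape matches the RGB
#' original), frequency-band filtering and corruptions (cutout,
#' Gaussian noise).
#'
#' @slot pixel,geometric,color,filter,corruption logical enable flags.
#' @slot scaleLogStd log-std of the log-normal iso/aniso scale factors.
#' @slot translationFrac std of fractional translations, as a fraction
#'   of each extent.
#' @slot intTranslateFrac maximum integer translation, as a fraction of
#'   each extent (draws are uniform integers within it).
#' @slot brightnessStd std of the normal additive brightness shift.
#' @slot contrastLogStd log-std of the log-normal contrast factor.
#' @slot bandGainLogStd log-std of the log-normal per-band gains.
#' @slot cutoutFrac cutout box edge as a fraction of each extent.
#' @slot noiseStdScale half-normal scale of the drawn noise std.
#' @slot axialRot90Only restrict pixel-level axial rotations to 90
#'   degree multiples (lattice-exact); a knob because the alternative —
#'   arbitrary in-plane angles — is handled by the geometric category.
#' @export
setClass("AugConfig",
  representation(
    pixel = "logical", geometric = "logical", color = "logical",
    filter = "logical", corruption = "logical",
    scaleLogStd = "numeric", translationFrac = "numeric",
    intTranslateFrac = "numeric", brightnessStd = "numeric",
    contrastLogStd = "numeric", bandGainLogStd = "numeric",
    cutoutFrac = "numeric", noiseStdScale = "numeric",
    axialRot90Only = "logical"
  )
)

setValidity("AugConfig", function(object) {
  strengths <- c(object@scaleLogStd, object@translationFrac,
                 object@intTranslateFrac, object@brightnessStd,
                 object@contrastLogStd, object@bandGainLogStd,
                 object@cutoutFrac, object@noiseStdScale)
  if (any(strengths < 0)) return("strength parameters must be >= 0")
  TRUE
})

#' Build an augmentation configuration
#'
#' @param preset `"none"` (all categories off), `"color_only"` (colour
#'   transforms only) or `"strong"` (everything on) — the three
#'   pipelines compared during training.
#' @param pixel,geometric,color,filter,corruption optional per-category
#'   overrides of the preset.
#' @param scaleLogStd,translationFrac,intTranslateFrac,brightnessStd
#'   strength knobs, see [AugConfig-class].
#' @param contrastLogStd,bandGainLogStd,cutoutFrac,noiseStdScale idem.
#' @param axialRot90Only see [AugConfig-class].
#' @return an [AugConfig-class] object.
#' @examples
#' augConfig("strong")
#' augConfig("color_only")
#' @export
augConfig <- function(preset = c("strong", "color_only", "none"),
                      pixel = NULL, geometric = NULL, color = NULL,
                      filter = NULL, corruption = NULL,
                      scaleLogStd = 0.2, translationFrac = 0.125,
                      intTranslateFrac = 0.125, brightnessStd = 0.2,
                      contrastLogStd = 0.5, bandGainLogStd = 1,
                      cutoutFrac = 0.5, noiseStdScale = 0.1,
                      axialRot90Only = TRUE) {
  preset <- match.arg(preset)
  flags <- switch(preset,
    none = rep(FALSE, 5),
    color_only = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    strong = rep(TRUE, 5))
  pick <- function(ov, def) if (is.null(ov)) def else isTRUE(ov)
  new("AugConfig",
      pixel = pick(pixel, flags[1]), geometric = pick(geometric, flags[2]),
      color = pick(color, flags[3]), filter = pick(filter, flags[4]),
      corruption = pick(corruption, flags[5]),
      scaleLogStd = scaleLogStd, translationFrac = translationFrac,
      intTranslateFrac = intTranslateFrac, brightnessStd = brightnessStd,
      contrastLogStd = contrastLogStd, bandGainLogStd = bandGainLogStd,
      cutoutFrac = cutoutFrac, noiseStdScale = noiseStdScale,
      axialRot90Only = axialRot90Only)
}

setMethod("show", "AugConfig", function(object) {
  on <- c(pixel = object@pixel, geometric = object@geometric,
          color = object@color, filter = object@filter,
          corruption = object@corruption)
  cat("AugConfig: categories on:",
      if (any(on)) paste(names(on)[on], collapse = ", ") else "(none)",
      "\n")
})

#' One sampled augmentation realization
#'
#' The concrete transform applied to one volume: a homogeneous 4x4
#' voxel-space geometry matrix (pixel-level and geometric factors
#' composed), a homogeneous 4x4 colour matrix acting on the RGB-lifted
#' intensity, per-band gains for the frequency filter, an optional
#' cutout centre and a Gaussian noise std.  When no per-transform
#' Bernoulli draw fires, the draw is the identity.
#'
#' @slot geom invertible 4x4 matrix on normalized (d, h, w) coordinates.
#' @slot color 4x4 matrix on homogeneous RGB intensity.
#' @slot bandGains positive per-band multipliers (low to high band).
#' @slot cutoutCenter fractional coordinates in \[0,1\]^3, or NA if no
#'   cutout fired.
#' @slot noiseStd non-negative Gaussian noise std (0 = none).
#' @export
setClass("AugDraw",
  representation(geom = "matrix", color = "matrix",
                 bandGains = "numeric", cutoutCenter = "numeric",
                 noiseStd = "numeric")
)

setValidity("AugDraw", function(object) {
  if (!all(dim(object@geom) == c(4L, 4L))) return("geom must be 4x4")
  if (abs(det(object@geom)) < 1e-12) return("geom must be invertible")
  if (!all(dim(object@color) == c(4L, 4L))) return("color must be 4x4")
  if (any(object@bandGains <= 0)) return("band gains must be > 0")
  if (object@noiseStd < 0) return("noiseStd must be >= 0")
  TRUE
})

identityDraw <- function(nBands = 4L) {
  new("AugDraw", geom = diag(4), color = diag(4),
      bandGains = rep(1, nBands), cutoutCenter = rep(NA_real_, 3),
      noiseStd = 0)
}

isIdentityDraw <- function(d) {
  identical(unname(d@geom), diag(4)) &&
    identical(unname(d@color), diag(4)) &&
    all(d@bandGains == 1) && all(is.na(d@cutoutCenter)) &&
    d@noiseStd == 0
}

setMethod("show", "AugDraw", function(object) {
  cat(sprintf(
    "AugDraw: %s geometry, %s colour, gains [%s], cutout %s, noise std %.3g\n",
    if (identical(unname(object@geom), diag(4))) "identity" else "warped",
    if (identical(unname(object@color), diag(4))) "identity" else "adjusted",
    paste(format(object@bandGains, digits = 3), collapse = ", "),
    if (all(is.na(object@cutoutCenter))) "none"
    else paste(format(object@cutoutCenter, digits = 2), collapse = ","),
    object@noiseStd))
})

## --- homogeneous matrix helpers (normalized [-1,1]^3 coords, axis
## --- order depth, height, width) ---------------------------------

mat4Scale <- function(s) diag(c(s, 1))

mat4Translate <- function(t) {
  m <- diag(4); m[1:3, 4] <- t; m
}

# rotation in the (height, width) plane = axial plane
mat4AxialRot <- function(theta) {
  m <- diag(4)
  c0 <- cos(theta); s0 <- sin(theta)
  # exact entries for multiples of pi/2 keep the lattice exact
  if (abs(theta %% (pi / 2)) < 1e-12 || abs(theta %% (pi / 2) - pi / 2) < 1e-12) {
    c0 <- round(c0); s0 <- round(s0)
  }
  m[2, 2] <- c0; m[2, 3] <- -s0; m[3, 2] <- s0; m[3, 3] <- c0
  m
}

mat4FlipSagittal <- function() diag(c(1, 1, -1, 1))

# uniform random rotation from a unit quaternion
mat4RandomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  r <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  m <- diag(4); m[1:3, 1:3] <- r; m
}

## --- colour matrices (homogeneous RGB) ---------------------------

colorBrightness <- function(b) mat4Translate(rep(b, 3))
colorContrast <- function(cfac) mat4Scale(rep(cfac, 3))

lumaAxis <- c(1, 1, 1) / sqrt(3)

colorLumaFlip <- function() {
  m <- diag(4)
  m[1:3, 1:3] <- diag(3) - 2 * tcrossprod(lumaAxis)
  m
}

# Rodrigues rotation about the luma axis; fixes gray values exactly
colorHueRotate <- function(theta) {
  k <- lumaAxis
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
               3, 3, byrow = TRUE)
  m <- diag(4)
  m[1:3, 1:3] <- diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
  m
}

colorSaturation <- function(s) {
  p <- tcrossprod(lumaAxis)
  m <- diag(4)
  m[1:3, 1:3] <- p + (diag(3) - p) * s
  m
}

#' Sample one augmentation draw
#'
#' Each enabled transform activates independently with probability `p`
#' (the shared augmentation probability the adaptive controller
#' drives).  Activated geometric factors compose in the fixed order
#' flip, axial 90-degree rotation, integer translation, isotropic
#' scale, arbitrary rotation, anisotropic scale, fractional
#' translation; colour factors compose brightness, contrast, luma
#' flip, hue rotation, saturation.  Uses the current RNG stream, so a
#' fixed seed gives an identical draw.
#'
#' @param cfg an [AugConfig-class].
#' @param p activation probability in \[0, 1\].
#' @param extent volume extent (D, H, W) the draw will be applied to
#'   (integer translations are quantized to this lattice).
#' @param nBands number of frequency bands of the filter stage.
#' @return an [AugDraw-class].
#' @examples
#' set.seed(1)
#' sampleDraw(augConfig("strong"), p = 0)   # identity
#' @export
sampleDraw <- function(cfg, p, extent = c(32L, 32L, 32L), nBands = 4L) {
  stopifnot(is(cfg, "AugConfig"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]")
  fires <- function() runif(1) < p
  geom <- diag(4)
  if (cfg@pixel) {
    if (fires()) geom <- mat4FlipSagittal() %*% geom
    if (fires()) {
      k <- sample(0:3, 1)
      geom <- mat4AxialRot(k * pi / 2) %*% geom
    }
    if (fires()) {
      tmax <- floor(extent * cfg@intTranslateFrac)
      tvox <- vapply(tmax, function(m) sample(seq(-m, m), 1), numeric(1))
      geom <- mat4Translate(2 * tvox / extent) %*% geom
    }
  }
  if (cfg@geometric) {
    if (fires()) geom <- mat4Scale(rep(exp(rnorm(1, 0, cfg@scaleLogStd)), 3)) %*% geom
    if (fires()) geom <- mat4RandomRotation() %*% geom
    if (fires()) geom <- mat4Scale(exp(rnorm(3, 0, cfg@scaleLogStd))) %*% geom
    if (fires()) geom <- mat4Translate(2 * rnorm(3, 0, cfg@translationFrac)) %*% geom
  }
  color <- diag(4)
  if (cfg@color) {
    if (fires()) color <- colorBrightness(rnorm(1, 0, cfg@brightnessStd)) %*% color
    if (fires()) color <- colorContrast(exp(rnorm(1, 0, cfg@contrastLogStd))) %*% color
    if (fires() && runif(1) < 0.5) color <- colorLumaFlip() %*% color
    if (fires()) color <- colorHueRotate(runif(1, -pi, pi)) %*% color
    if (fires()) color <- colorSaturation(exp(rnorm(1, 0, cfg@scaleLogStd))) %*% color
  }
  gains <- rep(1, nBands)
  if (cfg@filter) {
    for (i in seq_len(nBands))
      if (fires()) gains[i] <- exp(rnorm(1, 0, cfg@bandGainLogStd))
  }
  center <- rep(NA_real_, 3)
  noiseStd <- 0
  if (cfg@corruption) {
    if (fires()) center <- runif(3)
    if (fires()) noiseStd <- abs(rnorm(1, 0, cfg@noiseStdScale))
  }
  new("AugDraw", geom = geom, color = color, bandGains = gains,
      cutoutCenter = center, noiseStd = noiseStd)
}
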