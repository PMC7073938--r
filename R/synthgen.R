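# Synthetic colorimetric sensor experiments.
#
# The generator emulates the statistical structure a real dye array produces:
# monotone per-channel responses to the adulteration level, strong
# collinearity across channels (every dye is cross-sensitive to many of the
# same volatiles), and enough noise that adjacent levels overlap.

# Normalized logistic ramp on [0,1]: 0 at level 0, 1 at level 1, increasing.
.logisticRamp <- function(level, mid, width) {
  lo <- plogis((0 - mid) / width)
  hi <- plogis((1 - mid) / width)
  (plogis((level - mid) / width) - lo) / (hi - lo)
}

#' Build a synthetic dye-array response model
#'
#' Draws, once from \code{seed}, a set of per-dye-channel monotone response
#' curves: each channel's mean colour shift is a non-negative mixture of
#' \code{nFactors} shared logistic ramps (midpoints spread over the level
#' range) plus a small channel-specific logistic term. The shared ramps make
#' the 3*nDyes channels strongly collinear, so that PCA on a generated
#' dataset concentrates ~90\% of the variance in few components, as real
#' cross-sensitive dye arrays do.
#'
#' @param nDyes number of dye spots (default 12, a 4 x 3 array).
#' @param nFactors number of shared latent factors (default 3).
#' @param noiseSd additive Gaussian noise SD in intensity units (default 4).
#' @param seed integer; fixes all drawn parameters.
#' @param maxShift upper bound on a channel's full-range mean shift
#'   (intensity units, default 35).
#' @param idioFraction share of each channel's amplitude assigned to its
#'   channel-specific (non-shared) term (default 0.35).
#' @return a \linkS4class{DyeResponseModel}.
#' @examples
#' m <- dyeResponseModel(seed = 7)
#' range(responseCurve(m, 0.6))
#' @export
dyeResponseModel <- function(nDyes = 12L, nFactors = 3L, noiseSd = 4,
                             seed = 101L, maxShift = 35, idioFraction = 0.35) {
  nDyes <- as.integer(nDyes); nFactors <- as.integer(nFactors)
  if (nDyes < 1L) .stopf("nDyes must be >= 1")
  if (nFactors < 1L) .stopf("nFactors must be >= 1")
  p <- 3L * nDyes
  .withSeed(seed, {
    baseline <- matrix(runif(nDyes * 3L, 60, 160), nDyes, 3L,
                       dimnames = list(NULL, c("R", "G", "B")))
    amplitude <- runif(p, 0.2, 1) * maxShift
    w <- matrix(runif(p * nFactors), p, nFactors)
    w <- w / rowSums(w)
    latent <- w * amplitude * (1 - idioFraction)
    factorMid <- seq(0.15, 0.85, length.out = nFactors)
    factorWidth <- rep(0.08, nFactors)
    idioAmplitude <- amplitude * idioFraction
    idioMid <- runif(p, 0.15, 0.85)
    idioWidth <- runif(p, 0.05, 0.15)
  })
  obj <- new("DyeResponseModel", nDyes = nDyes, baseline = baseline,
             latentLoadings = latent, factorMid = factorMid,
             factorWidth = factorWidth, idioAmplitude = idioAmplitude,
             idioMid = idioMid, idioWidth = idioWidth,
             noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Mean colour-change profile at a given adulteration level
#'
#' The noise-free response: the expected 3N-vector of per-channel colour
#' shifts at \code{level}, clamped to [0, 255]. Strictly increasing in
#' \code{level} channel-wise (before clamping) whenever any loading is
#' positive.
#'
#' @param model a \linkS4class{DyeResponseModel}.
#' @param level adulteration fraction in [0,1].
#' @return named numeric vector of length \code{3 * nDyes}, channel-major.
#' @export
responseCurve <- function(model, level) {
  if (length(level) != 1L || is.na(level) || level < 0 || level > 1)
    .stopf("level must be a single value in [0,1]")
  g <- .logisticRamp(level, model@factorMid, model@factorWidth)
  gi <- .logisticRamp(level, model@idioMid, model@idioWidth)
  mu <- drop(model@latentLoadings %*% g) + model@idioAmplitude * gi
  mu <- pmin(pmax(mu, 0), 255)
  names(mu) <- .featureNames(model@nDyes)
  mu
}

#' Simulate one colour-change profile
#'
#' Adds clamped Gaussian measurement noise to \code{\link{responseCurve}}.
#' Uses R's current random stream; wrap in \code{set.seed()} (or use
#' \code{\link{generateDataset}}) for reproducibility. With
#' \code{noiseSd = 0} the result is the response curve itself, so repeated
#' calls at the same level are identical.
#'
#' @inheritParams responseCurve
#' @return named numeric vector of length \code{3 * nDyes} in [0, 255].
#' @export
simulateProfile <- function(model, level) {
  mu <- responseCurve(model, level)
  if (model@noiseSd > 0)
    mu <- pmin(pmax(mu + rnorm(length(mu), 0, model@noiseSd), 0), 255)
  mu
}

#' Generate a synthetic adulteration experiment
#'
#' Simulates \code{nPerLevel} replicate colour-change profiles at each level
#' of \code{levels}. The defaults emulate the standard design: six pork
#' fractions 0\%-100\% in 20\% steps with 14 replicates each, 84 samples in
#' total. Categories follow the fixed rule: fraction 0 is \code{pure_beef},
#' fraction 1 is \code{pure_pork}, anything between is \code{mixture}.
#'
#' @param levels distinct adulteration fractions in [0,1].
#' @param nPerLevel replicates per level (>= 1).
#' @param model a \linkS4class{DyeResponseModel}.
#' @param seed integer; the dataset is bit-identical under the same seed and
#'   parameters.
#' @return a \linkS4class{SensorProfileSet} with generator provenance in
#'   \code{metadata()}.
#' @examples
#' ds <- generateDataset(seed = 1)
#' ncol(ds)  # 84
#' @export
generateDataset <- function(levels = seq(0, 1, by = 0.2), nPerLevel = 14L,
                            model = dyeResponseModel(), seed = 1L) {
  if (length(levels) == 0L) .stopf("levels must be non-empty")
  if (anyDuplicated(levels)) .stopf("levels must be distinct")
  if (any(levels < 0 | levels > 1)) .stopf("levels must lie in [0,1]")
  nPerLevel <- as.integer(nPerLevel)
  if (is.na(nPerLevel) || nPerLevel < 1L) .stopf("nPerLevel must be >= 1")
  lev <- rep(levels, each = nPerLevel)
  prof <- .withSeed(seed,
    vapply(lev, function(l) simulateProfile(model, l),
           numeric(3L * model@nDyes)))
  SensorProfileSet(prof, level = lev,
                   provenance = list(levels = levels, nPerLevel = nPerLevel,
                                     noiseSd = model@noiseSd,
                                     modelSeed = model@seed, seed = seed))
}

#' Render a before/after image pair for a profile
#'
#' Inverts the difference-imaging readout: draws uniform-coloured discs on a
#' white canvas, with the after-exposure disc colours equal to baseline +
#' profile per channel. Extracting features from the pair with
#' \code{\link{differenceProfile}} recovers the profile up to 8-bit rounding
#' (at most 0.5 intensity units per feature).
#'
#' @param profile 3N colour-change vector, channel-major.
#' @param grid a \linkS4class{SpotGrid} with N spots.
#' @param baseline N x 3 matrix of before-exposure spot colours.
#' @param dpi resolution metadata stamped on both images.
#' @return list with \code{before} and \code{after}
#'   \linkS4class{SensorArrayImage}s.
#' @export
renderArrayPair <- function(profile, grid, baseline, dpi = 400L) {
  n <- nrow(grid@centers)
  if (length(profile) != 3L * n)
    .stopf("profile length %d does not match %d spots", length(profile), n)
  baseline <- round(as.matrix(baseline))  # the scanner sees 8-bit baselines
  if (!all(dim(baseline) == c(n, 3L))) .stopf("baseline must be %d x 3", n)
  shift <- matrix(profile, nrow = n)  # channel-major unpack: spots x RGB
  after <- baseline + shift
  if (any(after > 255) || any(baseline < 0))
    .stopf("baseline + profile exceeds the 8-bit range [0,255]")
  r <- grid@radiusPx
  H <- max(grid@centers[, 1]) + r + 5L
  W <- max(grid@centers[, 2]) + r + 5L
  if (min(grid@centers) < r) .stopf("spot discs extend past the image edge")
  paint <- function(colors) {
    img <- array(255, dim = c(H, W, 3L))
    off <- .discOffsets(r)
    for (i in seq_len(n)) {
      rows <- grid@centers[i, 1] + off[, 1] + 1L
      cols <- grid@centers[i, 2] + off[, 2] + 1L
      for (ch in 1:3) img[cbind(rows, cols, ch)] <- colors[i, ch]
    }
    img
  }
  list(before = SensorArrayImage(paint(baseline), "before", dpi),
       after = SensorArrayImage(paint(round(after)), "after", dpi))
}
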