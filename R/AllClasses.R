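#' SensorProfileSet: a container for colour-change profiles
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"profiles"}
#' (features in rows, samples in columns). Rows are the 3N colour-change
#' features in channel-major order (all \eqn{\Delta R}, then \eqn{\Delta G},
#' then \eqn{\Delta B}, spots in row-major grid order); columns carry the
#' per-sample metadata \code{sample_id}, \code{level} (pork mass fraction in
#' [0,1]) and \code{category} (\code{pure_beef}, \code{mixture},
#' \code{pure_pork}).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{generateDataset}}, \code{\link{readProfileTable}}
#' @export
setClass("SensorProfileSet", contains = "SummarizedExperiment")

setValidity("SensorProfileSet", function(object) {
  msg <- character()
  if (!"profiles" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'profiles' is required")
  cd <- colData(object)
  need <- c("sample_id", "level", "category")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  lev <- cd$level
  if (any(lev < 0 | lev > 1)) msg <- c(msg, "levels must lie in [0,1]")
  expect <- as.character(.categoryFromLevel(lev))
  if (!identical(as.character(cd$category), expect))
    msg <- c(msg, "category labels inconsistent with levels (0 -> pure_beef, 1 -> pure_pork, else mixture)")
  if (nrow(object) %% 3L != 0L)
    msg <- c(msg, "feature count must be a multiple of 3 (R, G, B per spot)")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorProfileSet
#'
#' @param profiles numeric matrix of colour-change values, either
#'   features x samples or samples x features (auto-detected from the
#'   \code{dyeNN_dX} feature names; supply features in rows when unnamed).
#' @param level numeric vector of adulteration fractions in [0,1], one per
#'   sample.
#' @param sampleId optional character vector of sample identifiers.
#' @param provenance optional list stored in \code{metadata()} describing how
#'   the data were produced (generator parameters, seeds, file paths).
#' @return a \linkS4class{SensorProfileSet}.
#' @export
SensorProfileSet <- function(profiles, level, sampleId = NULL, provenance = list()) {
  profiles <- as.matrix(profiles)
  featLike <- function(nm) !is.null(nm) && all(grepl("^dye[0-9]+_d[RGB]$", nm))
  if (featLike(colnames(profiles)) && !featLike(rownames(profiles)))
    profiles <- t(profiles)
  nS <- ncol(profiles)
  if (length(level) != nS)
    .stopf("length(level) [%d] != number of samples [%d]", length(level), nS)
  if (is.null(sampleId)) sampleId <- sprintf("S%03d", seq_len(nS))
  if (is.null(rownames(profiles)))
    rownames(profiles) <- .featureNames(nrow(profiles) %/% 3L)
  colnames(profiles) <- sampleId
  cd <- S4Vectors::DataFrame(sample_id = sampleId, level = as.numeric(level),
                             category = .categoryFromLevel(level),
                             row.names = sampleId)
  se <- SummarizedExperiment(assays = list(profiles = profiles), colData = cd)
  out <- new("SensorProfileSet", se)
  metadata(out)$provenance <- provenance
  validObject(out)
  out
}

#' @describeIn SensorProfileSet samples x features profile matrix.
#' @param x a \code{SensorProfileSet}.
#' @export
profileMatrix <- function(x) t(assay(x, "profiles"))

#' @describeIn SensorProfileSet per-sample adulteration fractions.
#' @export
adulterationLevel <- function(x) colData(x)$level

#' @describeIn SensorProfileSet per-sample category factor.
#' @export
sampleCategory <- function(x) colData(x)$category

#' @describeIn SensorProfileSet number of dye spots (features / 3).
#' @export
nSpots <- function(x) nrow(x) %/% 3L

setMethod("show", "SensorProfileSet", function(object) {
  cat(sprintf("SensorProfileSet: %d samples x %d colour-change features (%d spots)\n",
              ncol(object), nrow(object), nSpots(object)))
  tab <- table(sampleCategory(object))
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  levels:", paste(sort(unique(adulterationLevel(object))), collapse = ", "), "\n")
})

#' DyeResponseModel: the synthetic dye-array response model
#'
#' Parameterizes how a simulated 12-dye colorimetric array responds to the
#' pork fraction of a minced-meat sample. Each of the 3N dye channels has a
#' monotone response curve in the adulteration level, built as a non-negative
#' combination of a small number of shared logistic latent factors (which
#' induces the strong collinearity real arrays show, because every dye is
#' cross-sensitive to many of the same volatiles) plus a small dye-specific
#' logistic term. Measurement noise is additive Gaussian, clamped to the
#' 8-bit range.
#'
#' @slot nDyes number of dye spots.
#' @slot baseline nDyes x 3 matrix of unexposed spot colours (0-255).
#' @slot latentLoadings 3*nDyes x nFactors non-negative loading matrix.
#' @slot factorMid,factorWidth logistic midpoint/width per latent factor.
#' @slot idioAmplitude,idioMid,idioWidth dye-channel-specific logistic term.
#' @slot noiseSd additive Gaussian noise SD (intensity units).
#' @slot seed integer used to draw the model parameters.
#' @seealso \code{\link{dyeResponseModel}}, \code{\link{responseCurve}}
#' @export
setClass("DyeResponseModel", representation(
  nDyes = "integer", baseline = "matrix",
  latentLoadings = "matrix", factorMid = "numeric", factorWidth = "numeric",
  idioAmplitude = "numeric", idioMid = "numeric", idioWidth = "numeric",
  noiseSd = "numeric", seed = "integer"))

setValidity("DyeResponseModel", function(object) {
  msg <- character()
  p <- 3L * object@nDyes
  if (object@nDyes < 1L) msg <- c(msg, "nDyes must be >= 1")
  if (!all(dim(object@baseline) == c(object@nDyes, 3L)))
    msg <- c(msg, "baseline must be nDyes x 3")
  if (any(object@baseline < 0 | object@baseline > 255))
    msg <- c(msg, "baseline colours must lie in [0,255]")
  if (nrow(object@latentLoadings) != p)
    msg <- c(msg, "latentLoadings must have 3*nDyes rows")
  if (any(object@latentLoadings < 0))
    msg <- c(msg, "latentLoadings must be non-negative (monotone responses)")
  if (length(object@factorMid) != ncol(object@latentLoadings) ||
      length(object@factorWidth) != ncol(object@latentLoadings))
    msg <- c(msg, "factorMid/factorWidth length must equal the factor count")
  if (length(object@idioAmplitude) != p) msg <- c(msg, "idioAmplitude must have length 3*nDyes")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DyeResponseModel", function(object) {
  cat(sprintf("DyeResponseModel: %d dyes, %d latent factors, noiseSd = %g, seed = %d\n",
              object@nDyes, ncol(object@latentLoadings), object@noiseSd, object@seed))
})

#' SpotGrid: layout of dye spots on the array image
#'
#' Spot centres use 0-based (row, col) pixel coordinates, row increasing
#' downward, and are ordered row-major (left-to-right within each grid row).
#'
#' @slot rows,cols grid dimensions.
#' @slot centers n x 2 integer matrix of 0-based (row, col) centres.
#' @slot radiusPx disc radius in pixels.
#' @seealso \code{\link{locateSpots}}
#' @export
setClass("SpotGrid", representation(rows = "integer", cols = "integer",
                                    centers = "matrix", radiusPx = "integer"))

setValidity("SpotGrid", function(object) {
  msg <- character()
  if (nrow(object@centers) != object@rows * object@cols)
    msg <- c(msg, "rows*cols must equal the number of centers")
  if (object@radiusPx < 0L) msg <- c(msg, "radiusPx must be >= 0")
  n <- nrow(object@centers)
  if (n > 1L) {
    d2min <- min(as.matrix(dist(object@centers))[upper.tri(diag(n))])
    if (d2min <= 2 * object@radiusPx)
      msg <- c(msg, "spot discs overlap: centre spacing must exceed 2*radiusPx")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpotGrid", function(object) {
  cat(sprintf("SpotGrid: %d x %d spots, radius %d px (%d px per disc)\n",
              object@rows, object@cols, object@radiusPx,
              discPixelCount(object@radiusPx)))
})

#' SensorArrayImage: an 8-bit RGB scan of the dye array
#'
#' @slot pixels H x W x 3 array, integer channel values in [0,255].
#' @slot phase \code{"before"} or \code{"after"} exposure.
#' @slot dpi scan resolution metadata.
#' @export
setClass("SensorArrayImage", representation(pixels = "array",
                                            phase = "character",
                                            dpi = "integer"))

setValidity("SensorArrayImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "pixels must be H x W x 3")
  if (any(object@pixels < 0 | object@pixels > 255))
    msg <- c(msg, "channel values must lie in [0,255]")
  if (!object@phase %in% c("before", "after"))
    msg <- c(msg, "phase must be 'before' or 'after'")
  if (length(msg)) msg else TRUE
})

#' @describeIn SensorArrayImage constructor.
#' @param pixels H x W x 3 numeric array in [0,255].
#' @param phase exposure phase, \code{"before"} or \code{"after"}.
#' @param dpi scan resolution (metadata only).
#' @export
SensorArrayImage <- function(pixels, phase = c("before", "after"), dpi = 400L) {
  obj <- new("SensorArrayImage", pixels = round(pixels),
             phase = match.arg(phase), dpi = as.integer(dpi))
  validObject(obj)
  obj
}

setMethod("show", "SensorArrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SensorArrayImage (%s): %d x %d px, %d dpi\n",
              object@phase, d[1], d[2], object@dpi))
})

#' PCAModel: fitted principal component decomposition
#'
#' Eigendecomposition of the sample covariance of the mean-centred feature
#' matrix. Component signs are fixed so each loading column's
#' largest-magnitude entry is positive.
#'
#' @slot center per-feature training mean.
#' @slot loadings orthonormal eigenvector matrix (features x components).
#' @slot eigenvalues descending, non-negative.
#' @slot contribution per-component share of the total variance.
#' @slot kSelected components retained for downstream models.
#' @seealso \code{\link{pcaFit}}, \code{\link{selectComponents}}
#' @export
setClass("PCAModel", representation(center = "numeric", loadings = "matrix",
                                    eigenvalues = "numeric",
                                    contribution = "numeric",
                                    kSelected = "integer"))

setValidity("PCAModel", function(object) {
  msg <- character()
  L <- object@loadings
  if (ncol(L) != length(object@eigenvalues))
    msg <- c(msg, "one eigenvalue per loading column required")
  G <- crossprod(L)
  if (max(abs(G - diag(ncol(L)))) > 1e-8)
    msg <- c(msg, "loading columns must be orthonormal (tol 1e-8)")
  ev <- object@eigenvalues
  if (is.unsorted(rev(ev), strictly = FALSE)) msg <- c(msg, "eigenvalues must be descending")
  if (any(ev < -1e-10)) msg <- c(msg, "eigenvalues must be non-negative")
  if (abs(sum(object@contribution) - 1) > 1e-8)
    msg <- c(msg, "contributions must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PCAModel", function(object) {
  cum <- cumsum(object@contribution)
  k <- object@kSelected
  cat(sprintf("PCAModel: %d features, %d components; k = %d (%.2f%% cumulative)\n",
              nrow(object@loadings), ncol(object@loadings), k, 100 * cum[k]))
})

#' NormalizationParams: per-column min-max state
#'
#' Fitted state for the [0,1] rescaling y = (x - xmin) / (xmax - xmin).
#'
#' @slot xmin,xmax per-column training extremes.
#' @seealso \code{\link{minmaxFit}}
#' @export
setClass("NormalizationParams", representation(xmin = "numeric", xmax = "numeric"))

setValidity("NormalizationParams", function(object) {
  if (length(object@xmin) != length(object@xmax)) return("xmin/xmax length mismatch")
  if (any(object@xmax < object@xmin)) return("xmax must be >= xmin per column")
  TRUE
})

#' FisherLDAModel: Fisher discriminant axes and class centroids
#'
#' Discriminant functions (DFs) maximize between-class relative to
#' within-class scatter; at most min(k-1, p) axes exist for k classes and p
#' input variables. Prediction assigns the class whose centroid is nearest
#' (Euclidean) in DF space.
#'
#' @slot dfCoefficients p x s projection matrix (unit-norm columns).
#' @slot s number of discriminant functions retained.
#' @slot classCentroids k x s matrix of class means in DF space.
#' @slot dfContribution per-DF share of discriminating power.
#' @slot classOrder fixed label order (also the tie-break order).
#' @export
setClass("FisherLDAModel", representation(dfCoefficients = "matrix",
                                          s = "integer",
                                          classCentroids = "matrix",
                                          dfContribution = "numeric",
                                          classOrder = "character"))

setValidity("FisherLDAModel", function(object) {
  msg <- character()
  k <- nrow(object@classCentroids); p <- nrow(object@dfCoefficients)
  if (object@s > min(k - 1L, p)) msg <- c(msg, "s must satisfy s <= min(k-1, p)")
  if (ncol(object@dfCoefficients) != object@s) msg <- c(msg, "s columns required")
  if (abs(sum(object@dfContribution) - 1) > 1e-8)
    msg <- c(msg, "dfContribution must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FisherLDAModel", function(object) {
  cat(sprintf("FisherLDAModel: %d inputs -> %d DFs; contributions %s\n",
              nrow(object@dfCoefficients), object@s,
              paste(sprintf("%.1f%%", 100 * object@dfContribution), collapse = ", ")))
})

#' ELMModel: extreme learning machine classifier
#'
#' Single hidden layer with randomly drawn, fixed input weights and biases;
#' sigmoid activation S(x) = 1 / (1 + exp(-x)); output weights are the
#' minimum-norm least-squares (pseudoinverse) solution against one-hot class
#' targets.
#'
#' Inputs are min-max normalized to [0, 1] (training extremes stored in the
#' model) before entering the random layer, so the sigmoid operates in its
#' responsive range regardless of the score scale.
#'
#' @slot inputWeights L x p matrix, drawn U(-1, 1).
#' @slot normIn \linkS4class{NormalizationParams} for the inputs.
#' @slot biases length-L offsets, drawn U(-1, 1).
#' @slot outputWeights L x k least-squares solution.
#' @slot L hidden-neuron count.
#' @slot classOrder fixed label order (also the tie-break order).
#' @slot seed RNG seed for the random layer.
#' @export
setClass("ELMModel", representation(inputWeights = "matrix", biases = "numeric",
                                    outputWeights = "matrix", L = "integer",
                                    normIn = "NormalizationParams",
                                    classOrder = "character", seed = "integer"))

setMethod("show", "ELMModel", function(object) {
  cat(sprintf("ELMModel: %d inputs, L = %d hidden (sigmoid), %d classes, seed = %d\n",
              ncol(object@inputWeights), object@L, ncol(object@outputWeights),
              object@seed))
})

#' BPANNModel: back-propagation network for level regression
#'
#' Topology p-h-1 with tanh hidden units and a linear output on min-max
#' normalized inputs and targets; trained by full-batch gradient descent with
#' momentum until the normalized-scale training MSE reaches
#' \code{targetError} or \code{maxEpochs} elapse.
#'
#' @slot W1,b1,W2,b2 layer weights and biases (W1: h x p, W2: 1 x h).
#' @slot normIn,normOut \linkS4class{NormalizationParams} for inputs/targets.
#' @slot hyper list: learning rate, momentum, targetError, maxEpochs, batch.
#' @slot seed RNG seed for the initialization.
#' @slot finalEpoch,finalMse training outcome.
#' @slot trace per-epoch normalized-scale training MSE.
#' @export
setClass("BPANNModel", representation(W1 = "matrix", b1 = "numeric",
                                      W2 = "matrix", b2 = "numeric",
                                      normIn = "NormalizationParams",
                                      normOut = "NormalizationParams",
                                      hyper = "list", seed = "integer",
                                      finalEpoch = "integer", finalMse = "numeric",
                                      trace = "numeric"))

setMethod("show", "BPANNModel", function(object) {
  cat(sprintf("BPANNModel: topology %d-%d-1 (tanh hidden), lr = %g, momentum = %g\n",
              ncol(object@W1), nrow(object@W1),
              object@hyper$learningRate, object@hyper$momentum))
  cat(sprintf("  stopped at epoch %d, training MSE %.3g (target %g)\n",
              object@finalEpoch, object@finalMse, object@hyper$targetError))
})

#' EvaluationReport: pipeline performance summary
#'
#' Aggregates identification rates (classifiers), RMSE and the r statistic
#' (regressor) on the training and prediction sets, plus confusion tables.
#'
#' @slot classification named list per classifier: rates, confusion tables,
#'   counts.
#' @slot regression list: rmse/r per set, predictions.
#' @slot info list: seeds, selected hyperparameters (k, L, h), split sizes.
#' @export
setClass("EvaluationReport", representation(classification = "list",
                                            regression = "list",
                                            info = "list"))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  for (nm in names(object@classification)) {
    cl <- object@classification[[nm]]
    cat(sprintf("  %-10s identification rate: training %.2f%% (%d/%d), prediction %.2f%% (%d/%d)\n",
                nm, cl$rate_train, cl$n_correct_train, cl$n_train,
                cl$rate_predict, cl$n_correct_predict, cl$n_predict))
  }
  if (length(object@regression)) {
    rg <- object@regression
    cat(sprintf("  %-10s RMSE: training %.3f, prediction %.3f; r: training %.2f, prediction %.2f\n",
                "bpann", rg$rmse_train, rg$rmse_predict, rg$r_train, rg$r_predict))
  }
  inf <- object@info
  if (length(inf))
    cat(sprintf("  k = %s PCs, L = %s hidden (ELM), h = %s hidden (BP-ANN), seed = %s\n",
                inf$k, inf$L, inf$h, inf$seed))
})
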