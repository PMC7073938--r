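# PCA preprocessing with cumulative-contribution component selection, and
# min-max normalization for network inputs.

#' Fit a principal component decomposition
#'
#' Eigendecomposition of the sample covariance (n-1 denominator) of the
#' mean-centred feature matrix. Dye-array data are strongly collinear, so a
#' handful of components typically carries ~90\% of the variance; the
#' per-component \code{contribution} (eigenvalue share of the trace) is what
#' \code{\link{selectComponents}} thresholds.
#'
#' Signs are not identifiable; each loading column is flipped, if needed, so
#' its largest-magnitude entry is positive, making fits reproducible.
#' A constant input matrix has no variance to decompose: all eigenvalues are
#' zero and contributions are defined as uniform, with a warning.
#'
#' @param X samples x features numeric matrix (>= 2 rows, no missing
#'   values), raw colour-change profiles or any feature table.
#' @param useCorrelation scale features to unit variance first (correlation-
#'   matrix PCA). Off by default: profiles share units (intensity), and raw
#'   covariance preserves the relative response magnitudes of the dyes.
#' @return a \linkS4class{PCAModel} with \code{kSelected} initialized to all
#'   components.
#' @examples
#' X <- matrix(rnorm(60), 10, 6)
#' m <- pcaFit(X)
#' sum(m@contribution)  # 1
#' @export
pcaFit <- function(X, useCorrelation = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) .stopf("pcaFit needs >= 2 samples")
  if (anyNA(X)) .stopf("pcaFit: missing values are not supported")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  if (useCorrelation) {
    s <- apply(Xc, 2L, sd)
    s[s == 0] <- 1
    Xc <- sweep(Xc, 2L, s, "/")
  }
  C <- crossprod(Xc) / (nrow(X) - 1L)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors
  # sign convention: largest-|entry| of each column positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  tot <- sum(ev)
  if (tot <= 0) {
    warning("constant input matrix: contributions defined as uniform")
    contribution <- rep(1 / length(ev), length(ev))
  } else contribution <- ev / tot
  rownames(V) <- colnames(X)
  colnames(V) <- sprintf("PC%d", seq_len(ncol(V)))
  obj <- new("PCAModel", center = center, loadings = V, eigenvalues = ev,
             contribution = contribution, kSelected = ncol(V))
  if (useCorrelation) attr(obj, "scale") <- s
  validObject(obj)
  obj
}

#' Number of components reaching a cumulative contribution
#'
#' The smallest k whose cumulative contribution rate (eigenvalue share) is
#' at least \code{threshold}; monotone non-decreasing in the threshold.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param threshold fraction in (0, 1].
#' @return integer k.
#' @examples
#' # eigenvalues 6, 3, 1: two components carry 90%
#' m <- pcaFit(matrix(rnorm(40), 10, 4))
#' selectComponents(m, 1.0) <= 4
#' @export
selectComponents <- function(model, threshold = 0.90) {
  if (threshold <= 0 || threshold > 1) .stopf("threshold must be in (0, 1]")
  cum <- cumsum(model@contribution)
  as.integer(which(cum >= threshold - 1e-12)[1])
}

#' Project data onto the leading principal components
#'
#' Centres \code{X} with the training mean and projects on the first
#' \code{k} loading columns. Score columns are uncorrelated with variances
#' equal to the eigenvalues (on the training data).
#'
#' @param model a \linkS4class{PCAModel}.
#' @param X samples x features matrix with the model's feature arity.
#' @param k components to keep (default \code{model@kSelected}).
#' @return samples x k score matrix.
#' @export
pcaTransform <- function(model, X, k = model@kSelected) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model@loadings))
    .stopf("feature arity mismatch: model has %d features, data %d",
           nrow(model@loadings), ncol(X))
  Xc <- sweep(X, 2L, model@center)
  s <- attr(model, "scale")
  if (!is.null(s)) Xc <- sweep(Xc, 2L, s, "/")
  Xc %*% model@loadings[, seq_len(k), drop = FALSE]
}

#' Fit per-column min-max normalization
#'
#' Records per-column training extremes for the rescaling
#' \eqn{y = (x - x_{min}) / (x_{max} - x_{min})}, which maps training
#' columns onto [0, 1].
#'
#' @param X samples x features matrix (>= 1 row).
#' @return a \linkS4class{NormalizationParams}.
#' @examples
#' p <- minmaxFit(matrix(c(2, 4, 6), 3, 1))
#' minmaxApply(p, matrix(c(2, 4, 6), 3, 1))  # 0, 0.5, 1
#' @export
minmaxFit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) .stopf("minmaxFit needs >= 1 row")
  obj <- new("NormalizationParams",
             xmin = apply(X, 2L, min), xmax = apply(X, 2L, max))
  validObject(obj)
  obj
}

#' @rdname minmaxFit
#' @param params a \linkS4class{NormalizationParams}.
#' @details Values outside the training range extrapolate linearly (no
#'   clamping), so prediction-set values may fall outside [0, 1]. A
#'   degenerate column (xmax = xmin) maps to 0, with a warning: an all-zero
#'   sensor channel should not abort an analysis.
#' @export
minmaxApply <- function(params, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(params@xmin)) .stopf("column arity mismatch")
  rng <- params@xmax - params@xmin
  deg <- rng == 0
  if (any(deg)) {
    warning(sprintf("%d degenerate column(s) (xmax = xmin) mapped to 0", sum(deg)))
    rng[deg] <- 1
  }
  Y <- sweep(sweep(X, 2L, params@xmin), 2L, rng, "/")
  Y[, deg] <- 0
  Y
}

#' @rdname minmaxFit
#' @param Y matrix on the normalized scale.
#' @details \code{minmaxInvert} is the exact algebraic inverse for
#'   non-degenerate columns; degenerate columns invert to \code{xmin}.
#' @export
minmaxInvert <- function(params, Y) {
  Y <- as.matrix(Y)
  if (ncol(Y) != length(params@xmin)) .stopf("column arity mismatch")
  rng <- params@xmax - params@xmin
  sweep(sweep(Y, 2L, rng, "*"), 2L, params@xmin, "+")
}

#' Persist or restore a PCA model as JSON
#'
#' @param model a \linkS4class{PCAModel}.
#' @param path JSON file path.
#' @return \code{readPCAModel}: the restored \linkS4class{PCAModel}.
#' @export
writePCAModel <- function(model, path) {
  jsonlite::write_json(list(center = model@center,
                            loadings = model@loadings,
                            eigenvalues = model@eigenvalues,
                            kSelected = model@kSelected,
                            featureNames = rownames(model@loadings)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePCAModel
#' @export
readPCAModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(j$loadings)
  rownames(L) <- j$featureNames
  center <- j$center
  names(center) <- j$featureNames
  colnames(L) <- sprintf("PC%d", seq_len(ncol(L)))
  ev <- pmax(j$eigenvalues, 0)
  contribution <- if (sum(ev) > 0) ev / sum(ev) else rep(1 / length(ev), length(ev))
  new("PCAModel", center = center, loadings = L, eigenvalues = ev,
      contribution = contribution, kSelected = as.integer(j$kSelected))
}
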