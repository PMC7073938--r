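# Fisher LDA with nearest-centroid assignment, and the extreme learning
# machine with hidden-neuron-count optimization.

.oneHot <- function(labels, classOrder = .CLASS_ORDER) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), classOrder)
  if (length(bad)) .stopf("unknown class label(s): %s", paste(bad, collapse = ", "))
  T <- matrix(0, length(labels), length(classOrder),
              dimnames = list(NULL, classOrder))
  T[cbind(seq_along(labels), match(labels, classOrder))] <- 1
  T
}

# argmax with ties resolved to the first class in classOrder (columns are
# already in that order, and which.max returns the first maximum).
.decodeClasses <- function(score, classOrder) {
  factor(classOrder[apply(score, 1L, which.max)], levels = classOrder)
}

#' Fit a Fisher linear discriminant model
#'
#' Discriminant axes solve the generalized eigenproblem of between-class
#' versus within-class scatter: directions that keep each class's projected
#' spread as small, and the spread between class means as large, as
#' possible. With k classes and p inputs at most s = min(k - 1, p) axes
#' carry discriminating power; all of them are retained, and each axis's
#' contribution is its eigenvalue's share.
#'
#' The solve whitens by the Cholesky factor of the within-class scatter; if
#' that scatter is singular a ridge of \code{1e-6 * trace / p} is added,
#' with a warning. Axes are unit-norm with the largest-magnitude coefficient
#' positive.
#'
#' @param scores samples x p numeric matrix (typically PCA scores).
#' @param labels class labels; every class needs >= 2 samples.
#' @param classOrder fixed label order, also the tie-break order.
#' @return a \linkS4class{FisherLDAModel}.
#' @examples
#' X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 3), 10))
#' m <- ldaFit(X, rep(c("pure_beef", "pure_pork"), each = 10))
#' m@s  # 1
#' @export
ldaFit <- function(scores, labels, classOrder = NULL) {
  X <- as.matrix(scores)
  labels <- as.character(labels)
  if (is.null(classOrder))
    classOrder <- if (all(labels %in% .CLASS_ORDER))
      intersect(.CLASS_ORDER, labels) else unique(labels)
  classes <- classOrder[classOrder %in% labels]
  k <- length(classes); p <- ncol(X)
  if (k < 2L) .stopf("ldaFit needs >= 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    .stopf("every class needs >= 2 samples (%s has %d)",
           names(counts)[which.min(counts)], min(counts))
  grand <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  means <- matrix(NA_real_, k, p, dimnames = list(classes, NULL))
  for (ci in seq_len(k)) {
    Xi <- X[labels == classes[ci], , drop = FALSE]
    mi <- colMeans(Xi)
    means[ci, ] <- mi
    Xic <- sweep(Xi, 2L, mi)
    Sw <- Sw + crossprod(Xic)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - grand)
  }
  R <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < sqrt(.Machine$double.eps * sum(diag(Sw)))) {
    warning("singular within-class scatter: adding ridge 1e-6 * trace / p")
    Sw <- Sw + diag(max(1e-6 * sum(diag(Sw)) / p, 1e-8), p)
    R <- chol(Sw)
  }
  # whiten: eigen of inv(R') Sb inv(R), map axes back through inv(R)
  B <- backsolve(R, t(backsolve(R, Sb, transpose = TRUE)), transpose = TRUE)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  s <- min(k - 1L, p)
  W <- backsolve(R, e$vectors[, seq_len(s), drop = FALSE])
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  for (j in seq_len(s)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  ev <- pmax(e$values[seq_len(s)], 0)
  contribution <- if (sum(ev) > 0) ev / sum(ev) else rep(1 / s, s)
  colnames(W) <- sprintf("DF%d", seq_len(s))
  obj <- new("FisherLDAModel", dfCoefficients = W, s = as.integer(s),
             classCentroids = means %*% W, dfContribution = contribution,
             classOrder = classes)
  validObject(obj)
  obj
}

#' Classify by nearest centroid in discriminant space
#'
#' Projects samples onto the discriminant functions and assigns each to the
#' class whose centroid is nearest in Euclidean distance; exact ties go to
#' the first class in \code{classOrder}.
#'
#' @param model a \linkS4class{FisherLDAModel}.
#' @param scores samples x p matrix with the model's input arity.
#' @return factor of predicted labels.
#' @export
ldaPredict <- function(model, scores) {
  X <- as.matrix(scores)
  if (ncol(X) != nrow(model@dfCoefficients))
    .stopf("input arity mismatch: model expects %d variables",
           nrow(model@dfCoefficients))
  D <- X %*% model@dfCoefficients
  cent <- model@classCentroids
  d2 <- outer(rowSums(D^2), rep(1, nrow(cent))) - 2 * D %*% t(cent) +
    outer(rep(1, nrow(D)), rowSums(cent^2))
  # ties (to numerical tolerance) resolve to the first class in classOrder
  pick <- apply(d2, 1L, function(d) {
    which(d <= min(d) + 1e-9 * max(1, min(d)))[1]
  })
  factor(model@classOrder[pick], levels = model@classOrder)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.elmHidden <- function(model, X) .sigmoid(X %*% t(model@inputWeights) +
                                            rep(model@biases, each = nrow(X)))

#' Fit an extreme learning machine classifier
#'
#' Input weights and hidden biases are drawn uniformly on [-1, 1] from
#' \code{seed} and never adjusted; with sigmoid hidden activations
#' S(x) = 1 / (1 + exp(-x)) the output weights are the minimum-norm
#' least-squares (Moore-Penrose) solution of H beta = T against one-hot
#' class targets, so fitting needs no iterative training. Training inputs
#' are min-max normalized to [0, 1] first (the extremes travel with the
#' model), keeping the random sigmoid layer away from saturation.
#'
#' @param scores samples x p training matrix (>= 2 samples).
#' @param labels training class labels.
#' @param L hidden-neuron count (>= 1). With L equal to the number of
#'   distinct training samples the hidden matrix is generically invertible
#'   and the training data are interpolated exactly.
#' @param seed integer; same seed, same model.
#' @param classOrder fixed label order, also the tie-break order.
#' @return an \linkS4class{ELMModel}.
#' @export
elmFit <- function(scores, labels, L, seed = 1L, classOrder = NULL) {
  X <- as.matrix(scores)
  L <- as.integer(L)
  if (L < 1L) .stopf("L must be >= 1")
  if (nrow(X) < 2L) .stopf("elmFit needs >= 2 samples")
  labels <- as.character(labels)
  if (is.null(classOrder))
    classOrder <- if (all(labels %in% .CLASS_ORDER))
      .CLASS_ORDER[.CLASS_ORDER %in% labels] else unique(labels)
  T <- .oneHot(labels, classOrder)
  p <- ncol(X)
  .withSeed(seed, {
    W <- matrix(runif(L * p, -1, 1), L, p)
    b <- runif(L, -1, 1)
  })
  normIn <- minmaxFit(X)
  model <- new("ELMModel", inputWeights = W, biases = b,
               outputWeights = matrix(0, L, length(classOrder)),
               L = L, normIn = normIn, classOrder = classOrder,
               seed = as.integer(seed))
  H <- .elmHidden(model, minmaxApply(normIn, X))
  model@outputWeights <- MASS::ginv(H) %*% T
  colnames(model@outputWeights) <- classOrder
  model
}

#' Network outputs of an ELM
#'
#' Raw per-class activations S(X W' + b) beta; rows are independent, so
#' permuting samples permutes outputs identically.
#'
#' @param model an \linkS4class{ELMModel}.
#' @param scores samples x p matrix.
#' @return samples x classes activation matrix.
#' @export
elmActivations <- function(model, scores) {
  X <- as.matrix(scores)
  if (ncol(X) != ncol(model@inputWeights))
    .stopf("input arity mismatch: model expects %d variables",
           ncol(model@inputWeights))
  .elmHidden(model, minmaxApply(model@normIn, X)) %*% model@outputWeights
}

#' @rdname elmActivations
#' @details \code{elmPredict} decodes by argmax over class columns; exact
#'   ties go to the first class in \code{classOrder}.
#' @return \code{elmPredict}: factor of predicted labels.
#' @export
elmPredict <- function(model, scores) {
  .decodeClasses(elmActivations(model, scores), model@classOrder)
}

#' Choose the ELM hidden-neuron count by validation RMSE
#'
#' Fits one model per candidate L (all from the same seed) and scores each
#' by the RMSE between the one-hot validation targets and the network
#' activations — the same criterion used when the hidden layer size of an
#' e-nose classifier is tuned against a held-out prediction set. Ties go to
#' the smallest L.
#'
#' @param scoresTrain,labelsTrain training data.
#' @param scoresVal,labelsVal validation data.
#' @param Lgrid candidate hidden-neuron counts (non-empty).
#' @param seed integer seed shared by all candidate fits.
#' @param classOrder fixed label order.
#' @return list: \code{L} (the winner), \code{rmse} (its validation RMSE),
#'   \code{trace} (data.frame of L vs RMSE), \code{model} (the refitted
#'   winner).
#' @export
elmSelectHidden <- function(scoresTrain, labelsTrain, scoresVal, labelsVal,
                            Lgrid, seed = 1L, classOrder = NULL) {
  if (length(Lgrid) == 0L) .stopf("Lgrid must be non-empty")
  Lgrid <- as.integer(sort(unique(Lgrid)))
  rmses <- numeric(length(Lgrid))
  for (i in seq_along(Lgrid)) {
    m <- elmFit(scoresTrain, labelsTrain, Lgrid[i], seed = seed,
                classOrder = classOrder)
    A <- elmActivations(m, scoresVal)
    T <- .oneHot(labelsVal, m@classOrder)
    rmses[i] <- sqrt(mean((A - T)^2))
  }
  best <- Lgrid[which.min(rmses)]  # first minimum = smallest L on ties
  list(L = best, rmse = min(rmses),
       trace = data.frame(L = Lgrid, rmse = rmses),
       model = elmFit(scoresTrain, labelsTrain, best, seed = seed,
                      classOrder = classOrder))
}
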