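# Back-propagation network regression of the adulteration level.
#
# Topology p-h-1: tanh hidden layer, linear output, trained by gradient
# descent with momentum on the mean squared error of min-max normalized
# inputs and targets. A tanh output would saturate before the normalized
# 0 and 1 targets of the pure meats, so the output stays linear.

.bpannForward <- function(w, Xn) {
  A1 <- tanh(Xn %*% t(w$W1) + rep(w$b1, each = nrow(Xn)))
  list(A1 = A1, yhat = drop(A1 %*% t(w$W2)) + w$b2)
}

# Loss and analytic gradients on the normalized scale; the central
# finite-difference check in the test suite validates these.
.bpannGrad <- function(w, Xn, yn) {
  n <- nrow(Xn)
  fw <- .bpannForward(w, Xn)
  r <- fw$yhat - yn
  dY <- 2 * r / n                       # d(mean(r^2)) / d(yhat)
  dZ1 <- (dY %o% drop(w$W2)) * (1 - fw$A1^2)
  list(loss = mean(r^2),
       gW1 = crossprod(dZ1, Xn), gb1 = colSums(dZ1),
       gW2 = matrix(dY %*% fw$A1, 1L), gb2 = sum(dY))
}

#' Train a back-propagation network for level regression
#'
#' Inputs and targets are min-max normalized to [0, 1] (training extremes
#' are stored in the model and applied to later data). Weights start at
#' U(-0.5, 0.5) from \code{seed}; each epoch applies the momentum update
#' \eqn{\Delta w_t = -\eta \nabla E + \mu \Delta w_{t-1}} and training stops
#' once the normalized-scale training MSE reaches \code{targetError}, or at
#' \code{maxEpochs}. Defaults are the standard small-network recipe for
#' e-nose regression: learning rate 0.1, momentum 0.1, allowable error
#' 0.0002, at most 10,000 epochs.
#'
#' @param scores samples x p training inputs (typically PCA scores).
#' @param levels adulteration fractions in [0, 1], one per sample.
#' @param hidden hidden-neuron count h (>= 1).
#' @param seed integer; identical seed, data and settings give identical
#'   weight trajectories.
#' @param learningRate,momentum,targetError,maxEpochs training
#'   hyperparameters.
#' @param batch \code{"full"} (default) accumulates the gradient over the
#'   whole training set per epoch; \code{"online"} updates sample by sample.
#' @return a \linkS4class{BPANNModel} carrying the training trace, final
#'   epoch and final MSE.
#' @examples
#' X <- matrix(runif(60), 20, 3)
#' m <- bpannTrain(X, rowMeans(X), hidden = 4, seed = 2, maxEpochs = 500)
#' m@finalMse < 0.01
#' @export
bpannTrain <- function(scores, levels, hidden, seed = 1L,
                       learningRate = 0.1, momentum = 0.1,
                       targetError = 2e-4, maxEpochs = 10000L,
                       batch = c("full", "online")) {
  batch <- match.arg(batch)
  X <- as.matrix(scores)
  y <- as.numeric(levels)
  if (length(y) != nrow(X)) .stopf("levels length must match the sample count")
  if (any(y < 0 | y > 1)) .stopf("levels must lie in [0,1]")
  h <- as.integer(hidden)
  if (h < 1L) .stopf("hidden must be >= 1")
  p <- ncol(X)
  normIn <- minmaxFit(X)
  normOut <- minmaxFit(matrix(y, ncol = 1L))
  Xn <- minmaxApply(normIn, X)
  yn <- drop(minmaxApply(normOut, matrix(y, ncol = 1L)))
  w <- .withSeed(seed, list(W1 = matrix(runif(h * p, -0.5, 0.5), h, p),
                            b1 = runif(h, -0.5, 0.5),
                            W2 = matrix(runif(h, -0.5, 0.5), 1L, h),
                            b2 = runif(1L, -0.5, 0.5)))
  v <- list(gW1 = 0 * w$W1, gb1 = 0 * w$b1, gW2 = 0 * w$W2, gb2 = 0)
  trace <- numeric(maxEpochs)
  epoch <- 0L
  mse <- .bpannGrad(w, Xn, yn)$loss
  while (epoch < maxEpochs && mse > targetError) {
    epoch <- epoch + 1L
    if (batch == "full") {
      g <- .bpannGrad(w, Xn, yn)
      v <- list(gW1 = -learningRate * g$gW1 + momentum * v$gW1,
                gb1 = -learningRate * g$gb1 + momentum * v$gb1,
                gW2 = -learningRate * g$gW2 + momentum * v$gW2,
                gb2 = -learningRate * g$gb2 + momentum * v$gb2)
      w <- list(W1 = w$W1 + v$gW1, b1 = w$b1 + v$gb1,
                W2 = w$W2 + v$gW2, b2 = w$b2 + v$gb2)
    } else {
      for (i in sample.int(nrow(Xn))) {
        g <- .bpannGrad(w, Xn[i, , drop = FALSE], yn[i])
        v <- list(gW1 = -learningRate * g$gW1 + momentum * v$gW1,
                  gb1 = -learningRate * g$gb1 + momentum * v$gb1,
                  gW2 = -learningRate * g$gW2 + momentum * v$gW2,
                  gb2 = -learningRate * g$gb2 + momentum * v$gb2)
        w <- list(W1 = w$W1 + v$gW1, b1 = w$b1 + v$gb1,
                  W2 = w$W2 + v$gW2, b2 = w$b2 + v$gb2)
      }
    }
    mse <- .bpannGrad(w, Xn, yn)$loss
    if (!is.finite(mse))
      .stopf("training diverged (non-finite loss) at epoch %d; lower the learning rate", epoch)
    trace[epoch] <- mse
  }
  new("BPANNModel", W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
      normIn = normIn, normOut = normOut,
      hyper = list(learningRate = learningRate, momentum = momentum,
                   targetError = targetError, maxEpochs = as.integer(maxEpochs),
                   batch = batch),
      seed = as.integer(seed), finalEpoch = epoch, finalMse = mse,
      trace = trace[seq_len(epoch)])
}

#' Predict adulteration levels
#'
#' Forward pass on normalized inputs followed by the inverse of the output
#' normalization. Predictions are not clamped, so values slightly outside
#' [0, 1] can occur near the pure meats.
#'
#' @param model a \linkS4class{BPANNModel}.
#' @param scores samples x p matrix with the model's input arity.
#' @return numeric vector of predicted fractions.
#' @export
bpannPredict <- function(model, scores) {
  X <- as.matrix(scores)
  if (ncol(X) != ncol(model@W1))
    .stopf("input arity mismatch: model expects %d variables", ncol(model@W1))
  Xn <- minmaxApply(model@normIn, X)
  w <- list(W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2)
  yn <- .bpannForward(w, Xn)$yhat
  drop(minmaxInvert(model@normOut, matrix(yn, ncol = 1L)))
}

#' Choose the hidden layer size by validation RMSE
#'
#' Trains one network per candidate h (all from the same seed) and scores
#' each by prediction RMSE on the validation set (level scale); ties go to
#' the smallest h. This is the "trial and error" topology search that, for
#' a 9-input e-nose model, typically lands on a 9-5-1 architecture.
#'
#' @param scoresTrain,levelsTrain training data.
#' @param scoresVal,levelsVal validation data.
#' @param hGrid candidate hidden sizes (non-empty).
#' @param seed integer seed shared by all candidate fits.
#' @param ... further arguments passed to \code{\link{bpannTrain}}.
#' @return list: \code{h}, \code{rmse}, \code{trace} (data.frame),
#'   \code{model} (the winning fit).
#' @export
bpannSelectHidden <- function(scoresTrain, levelsTrain, scoresVal, levelsVal,
                              hGrid, seed = 1L, ...) {
  if (length(hGrid) == 0L) .stopf("hGrid must be non-empty")
  hGrid <- as.integer(sort(unique(hGrid)))
  fits <- vector("list", length(hGrid))
  rmses <- numeric(length(hGrid))
  for (i in seq_along(hGrid)) {
    fits[[i]] <- bpannTrain(scoresTrain, levelsTrain, hGrid[i], seed = seed, ...)
    rmses[i] <- rmse(levelsVal, bpannPredict(fits[[i]], scoresVal))
  }
  best <- which.min(rmses)  # first minimum = smallest h on ties
  list(h = hGrid[best], rmse = rmses[best],
       trace = data.frame(h = hGrid, rmse = rmses), model = fits[[best]])
}
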