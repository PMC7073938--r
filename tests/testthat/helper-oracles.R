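# Independent brute-force oracles. Deliberately naive: explicit loops,
# characteristic-polynomial root finding, inverse iteration, explicit
# matrix inversion — none of them share code paths with the package.

# covariance assembled entry by entry (n-1 denominator)
oracleCovariance <- function(X) {
  n <- nrow(X); p <- ncol(X)
  m <- numeric(p)
  for (j in 1:p) for (i in 1:n) m[j] <- m[j] + X[i, j] / n
  C <- matrix(0, p, p)
  for (j in 1:p) for (k in 1:p) {
    s <- 0
    for (i in 1:n) s <- s + (X[i, j] - m[j]) * (X[i, k] - m[k])
    C[j, k] <- s / (n - 1)
  }
  C
}

# polynomial arithmetic on coefficient vectors (ascending powers)
polyAdd <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b)))
}
polyMul <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1)
  for (i in seq_along(a)) for (j in seq_along(b))
    out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
  out
}

# determinant of a matrix of polynomials, by cofactor expansion
polyDet <- function(ent) {
  p <- nrow(ent)
  if (p == 1L) return(ent[[1, 1]])
  acc <- 0
  for (j in 1:p) {
    minor <- ent[-1, -j, drop = FALSE]
    term <- polyMul(ent[[1, j]], polyDet(minor))
    if (j %% 2 == 0) term <- -term
    acc <- polyAdd(acc, term)
  }
  acc
}

# eigenvalues of symmetric C as roots of det(C - lambda I), descending
oracleEigenvalues <- function(C) {
  p <- nrow(C)
  ent <- vector("list", p * p)
  dim(ent) <- c(p, p)
  for (i in 1:p) for (j in 1:p)
    ent[[i, j]] <- if (i == j) c(C[i, j], -1) else C[i, j]
  sort(Re(polyroot(polyDet(ent))), decreasing = TRUE)
}

# eigenvector by inverse iteration at a slightly shifted eigenvalue
oracleEigenvector <- function(C, lambda) {
  p <- nrow(C)
  A <- C - (lambda + 1e-8 * max(1, abs(lambda))) * diag(p)
  v <- rep(1, p) / sqrt(p)
  for (it in 1:8) {
    v <- solve(A, v)
    v <- v / sqrt(sum(v^2))
  }
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v
}

# Fisher LDA axes via explicit inversion: eigen of inv(Sw) Sb with scatter
# matrices accumulated class by class
oracleLDAaxes <- function(X, labels, s) {
  p <- ncol(X)
  classes <- unique(labels)
  grand <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in classes) {
    Xi <- X[labels == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    for (i in seq_len(nrow(Xi)))
      Sw <- Sw + tcrossprod(Xi[i, ] - mi)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - grand)
  }
  e <- eigen(solve(Sw) %*% Sb)
  ord <- order(Re(e$values), decreasing = TRUE)[seq_len(s)]
  V <- Re(e$vectors[, ord, drop = FALSE])
  for (j in seq_len(s)) {
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# central finite differences of the BP-ANN training loss in weight space
fdGradient <- function(w, Xn, yn, eps = 1e-6) {
  lossAt <- function(w) {
    A1 <- tanh(Xn %*% t(w$W1) + rep(w$b1, each = nrow(Xn)))
    yhat <- drop(A1 %*% t(w$W2)) + w$b2
    mean((yhat - yn)^2)
  }
  g <- lapply(w, function(x) x * 0)
  for (nm in names(w)) for (i in seq_along(w[[nm]])) {
    wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
    wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
    g[[nm]][i] <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
  }
  g
}

# disc mean by scanning every pixel of the image
bruteSpotMean <- function(image, center, radius) {
  d <- dim(image@pixels)
  acc <- c(0, 0, 0); cnt <- 0
  for (r in 1:d[1]) for (co in 1:d[2]) {
    if ((r - 1 - center[1])^2 + (co - 1 - center[2])^2 <= radius^2) {
      acc <- acc + image@pixels[r, co, ]
      cnt <- cnt + 1
    }
  }
  acc / cnt
}

# random SensorArrayImage
randomImage <- function(h, w, phase = "before") {
  SensorArrayImage(array(sample(0:255, h * w * 3, replace = TRUE),
                         dim = c(h, w, 3)), phase)
}
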