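test_that("Fisher LDA retains s = min(k-1, p) axes with unit contributions", {
  set.seed(41)
  X <- rbind(matrix(rnorm(27, 0), 9, 3), matrix(rnorm(27, 2), 9, 3),
             matrix(rnorm(27, 4), 9, 3))
  y <- rep(c("pure_beef", "mixture", "pure_pork"), each = 9)
  m <- ldaFit(X, y)
  expect_identical(m@s, 2L)  # 3 groups: two discriminant functions
  expect_equal(sum(m@dfContribution), 1)
  expect_lte(m@s, min(3 - 1, ncol(X)))

  # k = 3 classes on 9 PCA-score inputs: still two DFs
  X9 <- cbind(X, matrix(rnorm(27 * 6), 27, 6))
  m9 <- ldaFit(X9, y)
  expect_identical(m9@s, 2L)
})

test_that("two isotropic clusters give the centroid-difference axis", {
  # symmetric points around each centre: within-class scatter is isotropic,
  # so the single DF must parallel the difference of the class means
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  mu1 <- c(0, 0); mu2 <- c(6, 3)
  X <- rbind(sweep(base, 2, mu1, "+"), sweep(base, 2, mu2, "+"))
  y <- rep(c("a", "b"), each = 4)
  m <- ldaFit(X, y, classOrder = c("a", "b"))
  axis <- m@dfCoefficients[, 1]
  dir <- (mu2 - mu1) / sqrt(sum((mu2 - mu1)^2))
  expect_equal(abs(sum(axis * dir)), 1, tolerance = 1e-10)
})

test_that("LDA axes match the explicit-inversion generalized-eigen oracle", {
  set.seed(43)
  for (rep in 1:10) {
    p <- sample(2:4, 1)
    k <- sample(2:3, 1)
    n <- 8L
    X <- do.call(rbind, lapply(seq_len(k), function(ci)
      matrix(rnorm(n * p, mean = 3 * ci), n, p)))
    y <- rep(letters[seq_len(k)], each = n)
    m <- ldaFit(X, y, classOrder = letters[seq_len(k)])
    V <- oracleLDAaxes(X, y, m@s)
    expect_equal(unname(m@dfCoefficients), V, tolerance = 1e-8)
  }
})

test_that("LDA prediction is nearest-centroid with a fixed tie order", {
  set.seed(44)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2), matrix(rnorm(20, 5, 0.1), 10, 2))
  y <- rep(c("pure_beef", "pure_pork"), each = 10)
  m <- ldaFit(X, y)
  # samples at the class centroids are assigned to those classes
  cent0 <- colMeans(X[1:10, ]); cent1 <- colMeans(X[11:20, ])
  expect_equal(as.character(ldaPredict(m, rbind(cent0, cent1))),
               c("pure_beef", "pure_pork"))
  # an equidistant sample goes to the first class in classOrder
  mid <- (cent0 + cent1) / 2
  expect_equal(as.character(ldaPredict(m, rbind(mid))), "pure_beef")

  # noiseless, linearly separable synthetic data (compact classes: one
  # profile per category) gives 100% training identification
  ds <- generateDataset(levels = c(0, 0.5, 1),
                        model = dyeResponseModel(noiseSd = 0, seed = 7), seed = 9)
  pca <- pcaFit(profileMatrix(ds))
  S <- pcaTransform(pca, profileMatrix(ds), selectComponents(pca, 0.99))
  mFull <- suppressWarnings(ldaFit(S, sampleCategory(ds)))
  expect_equal(as.character(ldaPredict(mFull, S)),
               as.character(sampleCategory(ds)))
})

test_that("singular within-class scatter falls back to a ridge", {
  X <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))  # zero within-class scatter
  expect_warning(m <- ldaFit(X, c("a", "a", "b", "b"), classOrder = c("a", "b")),
                 "ridge")
  expect_identical(m@s, 1L)
})

test_that("the ELM sigmoid layer and seeding follow their contracts", {
  expect_equal(chromanose:::.sigmoid(0), 0.5)
  set.seed(45)
  X <- matrix(rnorm(30), 10, 3)
  y <- rep(c("pure_beef", "mixture"), 5)
  m1 <- elmFit(X, y, L = 6, seed = 3)
  m2 <- elmFit(X, y, L = 6, seed = 3)
  expect_identical(m1@inputWeights, m2@inputWeights)
  expect_identical(m1@outputWeights, m2@outputWeights)
  m3 <- elmFit(X, y, L = 6, seed = 4)
  expect_false(identical(m1@inputWeights, m3@inputWeights))
  expect_true(all(abs(m1@inputWeights) <= 1))
})

test_that("ELM with L = n interpolates the training labels", {
  set.seed(46)
  for (rep in 1:5) {
    n <- 12L
    X <- matrix(rnorm(n * 3), n, 3)
    y <- sample(c("pure_beef", "mixture", "pure_pork"), n, replace = TRUE)
    while (length(unique(y)) < 3) y <- sample(c("pure_beef", "mixture", "pure_pork"), n, replace = TRUE)
    m <- elmFit(X, y, L = n, seed = rep)
    expect_equal(as.character(elmPredict(m, X)), y)
  }
})

test_that("ELM residuals are orthogonal to the hidden column space", {
  set.seed(47)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(c("pure_beef", "mixture"), 10)
  m <- elmFit(X, y, L = 5, seed = 2)
  H <- chromanose:::.elmHidden(m, minmaxApply(m@normIn, X))
  T <- chromanose:::.oneHot(y, m@classOrder)
  R <- H %*% m@outputWeights - T
  expect_lt(max(abs(crossprod(H, R))), 1e-6)
})

test_that("ELM predictions are row-independent", {
  set.seed(48)
  X <- matrix(rnorm(36), 12, 3)
  y <- rep(c("pure_beef", "mixture", "pure_pork"), 4)
  m <- elmFit(X, y, L = 8, seed = 5)
  perm <- sample(12)
  expect_identical(elmPredict(m, X)[perm], elmPredict(m, X[perm, ]))
})

test_that("hidden-neuron selection minimizes validation RMSE reproducibly", {
  set.seed(49)
  ds <- generateDataset(seed = 15)
  pca <- pcaFit(profileMatrix(ds))
  S <- pcaTransform(pca, profileMatrix(ds), selectComponents(pca, 0.9))
  sp <- splitDataset(ds, "category", seed = 2)
  sTr <- S[sp$trainIds, ]; sPr <- S[sp$predictIds, ]
  yTr <- sampleCategory(sp$train); yPr <- sampleCategory(sp$predict)

  # singleton grid returns its only candidate
  one <- elmSelectHidden(sTr, yTr, sPr, yPr, Lgrid = 1L, seed = 1)
  expect_identical(one$L, 1L)

  sel1 <- elmSelectHidden(sTr, yTr, sPr, yPr, Lgrid = seq(5, 30, 5), seed = 1)
  sel2 <- elmSelectHidden(sTr, yTr, sPr, yPr, Lgrid = seq(5, 30, 5), seed = 1)
  expect_identical(sel1$L, sel2$L)
  expect_equal(sel1$trace, sel2$trace)
  expect_identical(sel1$L, sel1$trace$L[which.min(sel1$trace$rmse)])
})

test_that("both classifiers are perfect on noiseless separable data", {
  ds <- generateDataset(levels = c(0, 0.5, 1),
                        model = dyeResponseModel(noiseSd = 0, seed = 11), seed = 13)
  pca <- pcaFit(profileMatrix(ds))
  S <- pcaTransform(pca, profileMatrix(ds), selectComponents(pca, 0.99))
  y <- sampleCategory(ds)
  lda <- suppressWarnings(ldaFit(S, y))
  expect_equal(mean(ldaPredict(lda, S) == y), 1)
  elm <- elmFit(S, y, L = 20, seed = 1)
  expect_equal(mean(elmPredict(elm, S) == y), 1)
})
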