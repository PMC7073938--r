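test_that("analytic gradients match central finite differences", {
  set.seed(51)
  for (rep in 1:5) {
    n <- 7L; p <- sample(2:4, 1); h <- sample(2:4, 1)
    Xn <- matrix(runif(n * p), n, p)
    yn <- runif(n)
    w <- list(W1 = matrix(runif(h * p, -0.5, 0.5), h, p),
              b1 = runif(h, -0.5, 0.5),
              W2 = matrix(runif(h, -0.5, 0.5), 1, h),
              b2 = runif(1, -0.5, 0.5))
    g <- chromanose:::.bpannGrad(w, Xn, yn)
    fd <- fdGradient(w, Xn, yn)
    for (nm in names(w)) {
      denom <- pmax(abs(fd[[nm]]), 1e-3)
      expect_lt(max(abs(g[[paste0("g", nm)]] - fd[[nm]]) / denom), 1e-5)
    }
  }
})

test_that("training is seed-deterministic and inert at zero learning rate", {
  set.seed(52)
  X <- matrix(runif(30), 10, 3)
  y <- runif(10)
  m1 <- bpannTrain(X, y, hidden = 3, seed = 5, maxEpochs = 50)
  m2 <- bpannTrain(X, y, hidden = 3, seed = 5, maxEpochs = 50)
  expect_identical(m1@W1, m2@W1)
  expect_identical(m1@trace, m2@trace)

  m0 <- bpannTrain(X, y, hidden = 3, seed = 5, learningRate = 0, momentum = 0,
                   maxEpochs = 10)
  init <- chromanose:::.withSeed(5, list(W1 = matrix(runif(9, -0.5, 0.5), 3, 3)))
  expect_equal(m0@W1, init$W1)
})

test_that("one momentum-free epoch on one sample reduces its error", {
  set.seed(53)
  X <- matrix(runif(3), 1, 3)
  y <- 0.4
  # a single training sample makes every min-max column degenerate; that
  # path warns by design
  m1 <- suppressWarnings(bpannTrain(X, y, hidden = 2, seed = 1,
                                    learningRate = 1e-3, momentum = 0,
                                    maxEpochs = 1, targetError = 0))
  m0 <- suppressWarnings(bpannTrain(X, y, hidden = 2, seed = 1,
                                    learningRate = 0, momentum = 0,
                                    maxEpochs = 1, targetError = 0))
  expect_lt(m1@finalMse, m0@finalMse)
})

test_that("a noiseless linear target is learned to the stopping error", {
  set.seed(54)
  X <- matrix(runif(90), 30, 3)
  y <- rowMeans(X)  # linear in the inputs, values inside [0,1]
  m <- bpannTrain(X, y, hidden = 4, seed = 3)
  expect_lte(m@finalMse, 2e-4)
  expect_lt(m@finalEpoch, 10000L)
  # converged training predictions obey the stopping rule on the raw scale too
  expect_lte(rmse(y, bpannPredict(m, X)),
             sqrt(2e-4) * (max(y) - min(y)) + 1e-9)
  # running-minimum of the trace is monotone non-increasing
  expect_true(all(diff(cummin(m@trace)) <= 0))
})

test_that("noiseless synthetic levels are recovered with RMSE < 0.02", {
  ds <- generateDataset(model = dyeResponseModel(noiseSd = 0, seed = 19),
                        nPerLevel = 2L, seed = 23)
  pca <- pcaFit(profileMatrix(ds))
  S <- pcaTransform(pca, profileMatrix(ds), selectComponents(pca, 0.999))
  lev <- adulterationLevel(ds)
  m <- bpannTrain(S, lev, hidden = 5, seed = 7)
  pred <- bpannPredict(m, S)
  expect_lt(rmse(lev, pred), 0.02)
  # predictions are monotone in the level across the grid means
  gridMeans <- tapply(pred, lev, mean)
  expect_equal(unname(cor(as.numeric(names(gridMeans)), gridMeans,
                          method = "spearman")), 1)
})

test_that("degenerate networks predict the inverse-normalized bias", {
  set.seed(55)
  X <- matrix(runif(30), 10, 3)
  y <- runif(10, 0.2, 0.8)
  m <- bpannTrain(X, y, hidden = 3, seed = 2, learningRate = 0, momentum = 0,
                  maxEpochs = 1)
  m@W2[] <- 0
  pred <- bpannPredict(m, X)
  want <- drop(minmaxInvert(m@normOut, matrix(m@b2)))
  expect_equal(pred, rep(want, 10), ignore_attr = TRUE)
})

test_that("hidden-size selection minimizes validation RMSE with smallest-h ties", {
  set.seed(56)
  ds <- generateDataset(model = dyeResponseModel(seed = 25), seed = 27)
  pca <- pcaFit(profileMatrix(ds))
  S <- pcaTransform(pca, profileMatrix(ds), selectComponents(pca, 0.9))
  sp <- splitDataset(ds, "level", seed = 4)
  sTr <- S[sp$trainIds, ]; sPr <- S[sp$predictIds, ]
  lTr <- adulterationLevel(sp$train); lPr <- adulterationLevel(sp$predict)

  one <- bpannSelectHidden(sTr, lTr, sPr, lPr, hGrid = 5L, seed = 1,
                           maxEpochs = 300)
  expect_identical(one$h, 5L)

  sel1 <- bpannSelectHidden(sTr, lTr, sPr, lPr, hGrid = c(2, 4, 6), seed = 1,
                            maxEpochs = 300)
  sel2 <- bpannSelectHidden(sTr, lTr, sPr, lPr, hGrid = c(2, 4, 6), seed = 1,
                            maxEpochs = 300)
  expect_identical(sel1$h, sel2$h)
  expect_equal(sel1$trace, sel2$trace)
  expect_identical(sel1$h, as.integer(sel1$trace$h[which.min(sel1$trace$rmse)]))
})
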