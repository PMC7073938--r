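# Splitting, evaluation metrics, and end-to-end orchestration.

#' Stratified train/prediction split
#'
#' Draws, within each stratum (category or level), a prediction subset of
#' size \code{round(predictFraction * n)} (at least 1), leaving the rest for
#' training. The default fraction 2/7 reproduces the standard 84-sample
#' design's 60/24 split when stratifying the (14, 56, 14) categories.
#'
#' @param x a \linkS4class{SensorProfileSet}.
#' @param stratifyBy \code{"category"} (classification) or \code{"level"}
#'   (regression).
#' @param predictFraction fraction held out per stratum, in (0, 1).
#' @param seed integer; identical seed, identical id sets.
#' @return list with \code{train} and \code{predict}
#'   \linkS4class{SensorProfileSet}s plus \code{trainIds}, \code{predictIds}.
#' @examples
#' sp <- splitDataset(generateDataset(seed = 1), seed = 3)
#' c(ncol(sp$train), ncol(sp$predict))  # 60 24
#' @export
splitDataset <- function(x, stratifyBy = c("category", "level"),
                         predictFraction = 2 / 7, seed = 1L) {
  stratifyBy <- match.arg(stratifyBy)
  if (predictFraction <= 0 || predictFraction >= 1)
    .stopf("split error: predictFraction must lie strictly between 0 and 1")
  strata <- if (stratifyBy == "category") as.character(sampleCategory(x))
            else as.character(adulterationLevel(x))
  ids <- colData(x)$sample_id
  predictIds <- character()
  .withSeed(seed, for (s in unique(strata)) {
    inS <- ids[strata == s]
    if (length(inS) < 2L)
      .stopf("split error: stratum '%s' has %d sample(s); >= 2 required",
             s, length(inS))
    nPred <- max(1L, round(predictFraction * length(inS)))
    if (nPred >= length(inS))
      .stopf("split error: stratum '%s' would have an empty training share", s)
    predictIds <- c(predictIds, sample(inS, nPred))
  })
  trainIds <- setdiff(ids, predictIds)
  list(train = x[, trainIds], predict = x[, predictIds],
       trainIds = trainIds, predictIds = predictIds)
}

#' Identification rate
#'
#' R = N1 / N2 x 100\%, the percentage of correctly identified samples.
#'
#' @param nCorrect N1, correctly identified samples (0 <= N1 <= N2).
#' @param nTotal N2, all samples in the set (>= 1).
#' @return percentage (full precision; reports print two decimals).
#' @examples
#' round(identificationRate(13, 24), 2)  # 54.17
#' round(identificationRate(46, 60), 2)  # 76.67
#' @export
identificationRate <- function(nCorrect, nTotal) {
  if (nTotal < 1) .stopf("nTotal must be >= 1")
  if (nCorrect < 0 || nCorrect > nTotal) .stopf("nCorrect must lie in [0, nTotal]")
  100 * nCorrect / nTotal
}

#' Root mean square error
#'
#' @param y reference values.
#' @param yhat predicted values, same length.
#' @return sqrt(mean((y - yhat)^2)).
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) .stopf("length mismatch: %d vs %d",
                                        length(y), length(yhat))
  if (length(y) < 1L) .stopf("rmse needs >= 1 value")
  sqrt(mean((y - yhat)^2))
}

#' The r statistic: 1 - SSres / SStot
#'
#' The goodness-of-fit statistic conventionally reported for e-nose
#' regression models, r = 1 - sum((yhat - y)^2) / sum((y - mean(y))^2).
#' Algebraically this is the coefficient of determination rather than
#' Pearson's correlation; it is implemented exactly as reported. Perfect
#' prediction gives 1; predicting the mean gives 0; it is unbounded below.
#'
#' @param y reference values (not all equal).
#' @param yhat predicted values, same length.
#' @return the r value.
#' @examples
#' predictionR(c(0, 1, 2), c(0, 1, 1))  # 0.5
#' @export
predictionR <- function(y, yhat) {
  if (length(y) != length(yhat)) .stopf("length mismatch: %d vs %d",
                                        length(y), length(yhat))
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) .stopf("r is undefined for constant reference values")
  1 - sum((yhat - y)^2) / sstot
}

#' Confusion table of predicted vs reference classes
#'
#' Rows are reference classes, columns predictions, both in
#' \code{classOrder}; row sums equal the per-class sample counts and the
#' trace divided by the total equals the identification rate / 100.
#'
#' @param reference,predicted label vectors of equal length.
#' @param classOrder fixed class ordering.
#' @return k x k integer matrix.
#' @export
confusionTable <- function(reference, predicted, classOrder = .CLASS_ORDER) {
  table(factor(as.character(reference), levels = classOrder),
        factor(as.character(predicted), levels = classOrder))
}

.classMetrics <- function(refTrain, predTrain, refPred, predPred, classOrder) {
  ctTrain <- confusionTable(refTrain, predTrain, classOrder)
  ctPred <- confusionTable(refPred, predPred, classOrder)
  list(rate_train = identificationRate(sum(diag(ctTrain)), length(refTrain)),
       rate_predict = identificationRate(sum(diag(ctPred)), length(refPred)),
       n_correct_train = sum(diag(ctTrain)), n_train = length(refTrain),
       n_correct_predict = sum(diag(ctPred)), n_predict = length(refPred),
       confusion_train = ctTrain, confusion_predict = ctPred)
}

#' Default pipeline configuration
#'
#' A nested list mirroring the stages: \code{generator} (levels,
#' nPerLevel, noiseSd, modelSeed), \code{pca} (threshold), \code{split}
#' (predictFraction), \code{elm} (Lgrid), \code{bpann} (hGrid plus any
#' \code{\link{bpannTrain}} hyperparameter). Any subset can be overridden;
#' \code{configFile} (YAML with the same block structure) takes precedence
#' over the defaults, and \code{...} over both.
#'
#' @param configFile optional YAML file path.
#' @param ... named blocks overriding individual entries.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(configFile = NULL, ...) {
  cfg <- list(
    generator = list(levels = seq(0, 1, by = 0.2), nPerLevel = 14L,
                     noiseSd = 4, modelSeed = 101L),
    features = NULL,  # CSV path; overrides the generator when set
    pca = list(threshold = 0.90),
    split = list(predictFraction = 2 / 7),
    elm = list(Lgrid = seq(5L, 45L, by = 5L)),
    bpann = list(hGrid = 2:8, maxEpochs = 2000L))
  if (!is.null(configFile))
    cfg <- modifyList(cfg, yaml::read_yaml(configFile))
  modifyList(cfg, list(...))
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on synthetic or tabulated data:
#' generate/load profiles, PCA with cumulative-contribution component
#' selection, stratified splitting, Fisher LDA and ELM classification
#' (hidden size tuned on the prediction set), BP-ANN level regression
#' (topology tuned on the prediction set), and all evaluation metrics.
#' One master \code{seed} deterministically derives the generator, split,
#' ELM and BP-ANN seeds, so a rerun with the same configuration reproduces
#' the report exactly.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @param seed master integer seed.
#' @param outDir optional directory; when given, writes
#'   \code{report.json}, \code{report.txt}, confusion tables (CSV), the
#'   feature table and the PCA model.
#' @return an \linkS4class{EvaluationReport}.
#' @examples
#' \donttest{
#' rep <- runPipeline(seed = 7)
#' rep
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), seed = 1L, outDir = NULL) {
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L, 4L))
  # data
  if (!is.null(config$features)) {
    ds <- readProfileTable(config$features)
  } else {
    g <- config$generator
    model <- dyeResponseModel(noiseSd = g$noiseSd, seed = g$modelSeed)
    ds <- generateDataset(levels = g$levels, nPerLevel = g$nPerLevel,
                          model = model, seed = seeds[1])
  }
  X <- profileMatrix(ds)
  # PCA
  pca <- pcaFit(X)
  k <- selectComponents(pca, config$pca$threshold)
  pca@kSelected <- k
  scores <- pcaTransform(pca, X, k)
  # classification: split stratified by category
  spC <- splitDataset(ds, "category", config$split$predictFraction, seeds[2])
  sTr <- scores[spC$trainIds, , drop = FALSE]
  sPr <- scores[spC$predictIds, , drop = FALSE]
  yTr <- sampleCategory(spC$train); yPr <- sampleCategory(spC$predict)
  lda <- ldaFit(sTr, yTr)
  ldaM <- .classMetrics(yTr, ldaPredict(lda, sTr), yPr, ldaPredict(lda, sPr),
                        lda@classOrder)
  ldaM$df_contribution <- lda@dfContribution
  elmSel <- elmSelectHidden(sTr, yTr, sPr, yPr, config$elm$Lgrid, seeds[3])
  elm <- elmSel$model
  elmM <- .classMetrics(yTr, elmPredict(elm, sTr), yPr, elmPredict(elm, sPr),
                        elm@classOrder)
  # regression: split stratified by level
  spR <- splitDataset(ds, "level", config$split$predictFraction, seeds[2])
  rTr <- scores[spR$trainIds, , drop = FALSE]
  rPr <- scores[spR$predictIds, , drop = FALSE]
  lTr <- adulterationLevel(spR$train); lPr <- adulterationLevel(spR$predict)
  bpArgs <- config$bpann[setdiff(names(config$bpann), "hGrid")]
  bpSel <- do.call(bpannSelectHidden,
                   c(list(rTr, lTr, rPr, lPr, hGrid = config$bpann$hGrid,
                          seed = seeds[4]), bpArgs))
  bp <- bpSel$model
  predTr <- bpannPredict(bp, rTr); predPr <- bpannPredict(bp, rPr)
  regression <- list(rmse_train = rmse(lTr, predTr),
                     rmse_predict = rmse(lPr, predPr),
                     r_train = predictionR(lTr, predTr),
                     r_predict = predictionR(lPr, predPr))
  report <- new("EvaluationReport",
                classification = list(lda = ldaM, elm = elmM),
                regression = regression,
                info = list(seed = seed, stageSeeds = seeds, k = k,
                            L = elmSel$L, h = bpSel$h,
                            n_train = length(spC$trainIds),
                            n_predict = length(spC$predictIds),
                            pca_cumulative = sum(pca@contribution[seq_len(k)])))
  if (!is.null(outDir)) .writeReport(report, ds, pca, outDir)
  report
}

.reportAsList <- function(report) {
  cl <- lapply(report@classification, function(m) {
    m$confusion_train <- as.data.frame.matrix(m$confusion_train)
    m$confusion_predict <- as.data.frame.matrix(m$confusion_predict)
    m
  })
  list(classification = cl, regression = report@regression,
       info = report@info)
}

.writeReport <- function(report, ds, pca, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.reportAsList(report),
                       file.path(outDir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  txt <- utils::capture.output(show(report))
  writeLines(txt, file.path(outDir, "report.txt"))
  for (nm in names(report@classification))
    write.csv(as.data.frame.matrix(report@classification[[nm]]$confusion_predict),
              file.path(outDir, sprintf("confusion_%s_predict.csv", nm)))
  writeProfileTable(ds, file.path(outDir, "features.csv"))
  writePCAModel(pca, file.path(outDir, "pca.json"))
  invisible(outDir)
}
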