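featureColumns <- function(table) {
  setdiff(colnames(table), c("patient_id", "segmentation_threshold", "label"))
}

#' Patient-grouped stratified train/test split
#'
#' Splits an augmented feature table 70/30 at the patient level: all three
#' segmentations of a patient land on the same side, and the test set is
#' stratified by class (round(0.3 * n) patients per class). With the
#' 34-patient cohort this gives 24 training patients (72 rows) and 10 test
#' patients (30 rows, 5 per class).
#'
#' @param table feature table from [extractCohortFeatures()].
#' @param trainFraction fraction of patients in the training set, 0.70.
#' @param seed integer seed.
#' @return list with data.frames \code{train} and \code{test}.
#' @export
splitCohort <- function(table, trainFraction = 0.7, seed = 1L) {
  stopifnot(all(c("patient_id", "label") %in% colnames(table)))
  perPatient <- unique(table[, c("patient_id", "label")])
  if (any(table(table$patient_id) != table(table$patient_id)[1]))
    stop("every patient must contribute the same number of rows")
  testIds <- withSeed(seed, {
    unlist(lapply(split(perPatient$patient_id, perPatient$label),
                  function(ids) {
                    nTest <- round((1 - trainFraction) * length(ids))
                    sample(ids, nTest)
                  }))
  })
  list(train = table[!table$patient_id %in% testIds, , drop = FALSE],
       test = table[table$patient_id %in% testIds, , drop = FALSE])
}

rfFit <- function(x, y, nTrees, maxnodes = NULL) {
  randomForest::randomForest(x = x, y = y, ntree = nTrees,
                             maxnodes = maxnodes)
}

#' Recursive feature elimination with random-forest importance
#'
#' Iteratively fits a random forest on the training rows and removes the
#' 10\% least important features (mean decrease in node impurity) until at
#' most \code{maxFeatures} remain. Deterministic under the seed. Label
#' columns and patient grouping are untouched: only training rows are
#' seen.
#'
#' @param train training feature table.
#' @param maxFeatures maximum surviving features, default 4.
#' @param nTrees trees per elimination step, default 100.
#' @param step fraction of features removed per round, default 0.1.
#' @param seed integer seed.
#' @return character vector of at most \code{maxFeatures} feature names.
#' @export
selectFeatures <- function(train, maxFeatures = 4L, nTrees = 100L,
                           step = 0.1, seed = 1L) {
  feats <- featureColumns(train)
  if (length(feats) <= maxFeatures) return(feats)
  y <- factor(train$label, levels = c("EP", "PSP"))
  withSeed(seed, {
    while (length(feats) > maxFeatures) {
      fit <- rfFit(train[, feats, drop = FALSE], y, nTrees)
      imp <- randomForest::importance(fit)[, 1]
      nDrop <- max(1L, min(floor(step * length(feats)),
                           length(feats) - maxFeatures))
      feats <- names(sort(imp, decreasing = TRUE))[
        seq_len(length(feats) - nDrop)]
    }
    feats
  })
}

# stratified patient-grouped fold assignment
groupedFolds <- function(patients, labels, k = 5L) {
  fold <- integer(length(patients))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  names(fold) <- patients
  fold
}

#' Fit the random-forest classifier and evaluate on held-out patients
#'
#' Chooses hyperparameters (trees in {100, 500}, depth unlimited or
#' shallow) by patient-grouped stratified 5-fold cross-validation accuracy
#' on the training table, reports training metrics from the pooled
#' held-out CV predictions of the winning configuration, refits on the
#' full training table, and evaluates once on the untouched test rows.
#' Metrics are row-level by default (each augmented segmentation counts);
#' \code{aggregate = "patient"} majority-votes over the three rows of each
#' patient.
#'
#' @param train,test feature tables from [splitCohort()].
#' @param features feature names to use (e.g. from [selectFeatures()]).
#' @param nTreesGrid,maxnodesGrid hyperparameter grid.
#' @param cvFolds folds, default 5.
#' @param seed integer seed.
#' @param aggregate "row" or "patient".
#' @return list: \code{selectedFeatures}, \code{classifier},
#'   \code{hyperparameters}, \code{trainMetrics} and \code{testMetrics}
#'   ([ClassificationMetrics-class]).
#' @export
fitAndEvaluate <- function(train, test, features,
                           nTreesGrid = c(100L, 500L),
                           maxnodesGrid = list(NULL, 32L),
                           cvFolds = 5L, seed = 1L,
                           aggregate = c("row", "patient")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(features %in% colnames(train)),
            all(features %in% colnames(test)))
  yTrain <- factor(train$label, levels = c("EP", "PSP"))
  yTest <- factor(test$label, levels = c("EP", "PSP"))
  withSeed(seed, {
    perPatient <- unique(train[, c("patient_id", "label")])
    foldOf <- groupedFolds(perPatient$patient_id, perPatient$label, cvFolds)
    rowFold <- foldOf[as.character(train$patient_id)]

    grid <- expand.grid(tree = seq_along(nTreesGrid),
                        node = seq_along(maxnodesGrid))
    cvPred <- vector("list", nrow(grid))
    cvProb <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      pred <- factor(rep(NA, nrow(train)), levels = levels(yTrain))
      prob <- numeric(nrow(train))
      for (f in seq_len(cvFolds)) {
        hold <- rowFold == f
        if (!any(hold) || all(hold)) next
        fit <- rfFit(train[!hold, features, drop = FALSE], yTrain[!hold],
                     nTreesGrid[grid$tree[g]],
                     maxnodesGrid[[grid$node[g]]])
        pred[hold] <- stats::predict(fit, train[hold, features, drop = FALSE])
        prob[hold] <- stats::predict(fit, train[hold, features, drop = FALSE],
                                     type = "prob")[, "PSP"]
      }
      cvPred[[g]] <- pred
      cvProb[[g]] <- prob
    }
    cvAcc <- vapply(cvPred, function(p) mean(p == yTrain, na.rm = TRUE), 0)
    best <- which.max(cvAcc)
    trainMetrics <- predictionMetrics(cvPred[[best]], yTrain, cvProb[[best]])

    finalFit <- rfFit(train[, features, drop = FALSE], yTrain,
                      nTreesGrid[grid$tree[best]],
                      maxnodesGrid[[grid$node[best]]])
    testPred <- stats::predict(finalFit, test[, features, drop = FALSE])
    testProb <- stats::predict(finalFit, test[, features, drop = FALSE],
                               type = "prob")[, "PSP"]
    if (aggregate == "patient") {
      agg <- aggregateByPatient(test$patient_id, testPred, testProb, yTest)
      testMetrics <- predictionMetrics(agg$pred, agg$truth, agg$prob)
    } else {
      testMetrics <- predictionMetrics(testPred, yTest, testProb)
    }
    list(selectedFeatures = features,
         classifier = "random forest",
         hyperparameters = list(nTrees = nTreesGrid[grid$tree[best]],
                                maxnodes = maxnodesGrid[[grid$node[best]]]),
         cvAccuracy = cvAcc[best],
         trainMetrics = trainMetrics,
         testMetrics = testMetrics)
  })
}

aggregateByPatient <- function(ids, pred, prob, truth) {
  sp <- split(seq_along(ids), ids)
  lvls <- levels(truth)
  list(pred = factor(vapply(sp, function(ix) {
         tab <- table(pred[ix])
         names(tab)[which.max(tab)]
       }, ""), levels = lvls),
       prob = vapply(sp, function(ix) mean(prob[ix]), 0),
       truth = factor(vapply(sp, function(ix) as.character(truth[ix[1]]), ""),
                      levels = lvls))
}

predictionMetrics <- function(pred, truth, prob = NULL) {
  pos <- truth == "PSP"
  predPos <- pred == "PSP"
  auc <- NA_real_
  if (!is.null(prob) && any(pos) && any(!pos)) {
    r <- rank(prob)
    auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
  }
  classificationMetrics(tp = sum(predPos & pos, na.rm = TRUE),
                        fp = sum(predPos & !pos, na.rm = TRUE),
                        fn = sum(!predPos & pos, na.rm = TRUE),
                        tn = sum(!predPos & !pos, na.rm = TRUE),
                        auc = auc)
}

#' End-to-end radiomics classification on a feature table
#'
#' The complete augmentation-aware workflow on an extracted feature table:
#' 70/30 patient-grouped stratified split, recursive feature elimination
#' to at most four features on the training side only, hyperparameter
#' choice by grouped 5-fold cross-validation, and a single evaluation on
#' the held-out patients.
#'
#' @param table feature table ([extractCohortFeatures()]).
#' @param seed integer seed driving split, selection and training.
#' @param maxFeatures cap on selected features, default 4.
#' @param permuteLabels if TRUE, patient labels are randomly permuted
#'   (at patient level) before the split - the leakage null control.
#' @param aggregate "row" or "patient" test aggregation.
#' @return [fitAndEvaluate()] report, plus the split sizes.
#' @export
runRadiomicsPipeline <- function(table, seed = 1L, maxFeatures = 4L,
                                 permuteLabels = FALSE,
                                 aggregate = c("row", "patient")) {
  aggregate <- match.arg(aggregate)
  if (permuteLabels) {
    perPatient <- unique(table[, c("patient_id", "label")])
    perm <- withSeed(seed * 7 + 13, sample(perPatient$label))
    names(perm) <- as.character(perPatient$patient_id)
    table$label <- perm[as.character(table$patient_id)]
  }
  sp <- splitCohort(table, seed = seed)
  feats <- selectFeatures(sp$train, maxFeatures = maxFeatures,
                          seed = seed + 1L)
  rep <- fitAndEvaluate(sp$train, sp$test, feats, seed = seed + 2L,
                        aggregate = aggregate)
  rep$nTrainRows <- nrow(sp$train)
  rep$nTestRows <- nrow(sp$test)
  rep
}
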