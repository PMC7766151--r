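# synthetic feature tables built directly (no imaging), 3 rows per patient
syntheticFeatureTable <- function(seed, nEP = 18, nPSP = 16, nFeat = 30,
                                  nInformative = 2, effect = 2) {
  withr::with_seed(seed, {
    n <- nEP + nPSP
    label <- c(rep("EP", nEP), rep("PSP", nPSP))
    rows <- do.call(rbind, lapply(seq_len(n), function(i) {
      base <- stats::rnorm(nFeat)
      if (label[i] == "PSP")
        base[seq_len(nInformative)] <- base[seq_len(nInformative)] + effect
      t(vapply(1:3, function(k) base + stats::rnorm(nFeat, sd = 0.2),
               numeric(nFeat)))
    }))
    colnames(rows) <- c(paste0("informative_", seq_len(nInformative)),
                        paste0("noise_", seq_len(nFeat - nInformative)))
    data.frame(patient_id = rep(seq_len(n), each = 3),
               segmentation_threshold = rep(c(1.4, 1.6, 1.8), n),
               label = rep(label, each = 3), rows, check.names = FALSE)
  })
}

test_that("the augmented cohort splits 72/30 with patient-level grouping", {
  ft <- syntheticFeatureTable(1)
  sp <- splitCohort(ft, seed = 3L)
  expect_equal(nrow(sp$train), 72)
  expect_equal(nrow(sp$test), 30)
  expect_length(intersect(unique(sp$train$patient_id),
                          unique(sp$test$patient_id)), 0)
  testPat <- unique(sp$test[, c("patient_id", "label")])
  expect_equal(unname(table(testPat$label)["PSP"]), 5, ignore_attr = TRUE)
  expect_equal(unname(table(testPat$label)["EP"]), 5, ignore_attr = TRUE)
})

test_that("feature elimination returns at most four features, identity below", {
  ft <- syntheticFeatureTable(2)
  sel <- selectFeatures(splitCohort(ft, seed = 1L)$train, seed = 5L)
  expect_lte(length(sel), 4)

  small <- ft[, c("patient_id", "segmentation_threshold", "label",
                  "informative_1", "informative_2", "noise_1", "noise_2")]
  expect_setequal(selectFeatures(small, seed = 5L),
                  c("informative_1", "informative_2", "noise_1", "noise_2"))
})

test_that("elimination recovers informative features across seeds", {
  hits <- vapply(1:10, function(s) {
    ft <- syntheticFeatureTable(100 + s)
    sel <- selectFeatures(splitCohort(ft, seed = s)$train, seed = s)
    any(startsWith(sel, "informative_"))
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("a separable cohort reaches perfect held-out classification", {
  ft <- syntheticFeatureTable(3, effect = 8, nFeat = 6)
  sp <- splitCohort(ft, seed = 2L)
  rep <- fitAndEvaluate(sp$train, sp$test,
                        c("informative_1", "informative_2"), seed = 4L)
  expect_equal(rep$testMetrics@metrics[["sensitivity"]], 1)
  expect_equal(rep$testMetrics@metrics[["specificity"]], 1)
  expect_equal(rep$classifier, "random forest")
  expect_lte(length(rep$selectedFeatures), 4)
})

test_that("training output is independent of test labels (no leakage)", {
  ft <- syntheticFeatureTable(4)
  sp <- splitCohort(ft, seed = 6L)
  sel1 <- selectFeatures(sp$train, seed = 9L)
  testScrambled <- sp$test
  testScrambled$label <- withr::with_seed(1, sample(testScrambled$label))
  sel2 <- selectFeatures(sp$train, seed = 9L)
  expect_identical(sel1, sel2)
  r1 <- fitAndEvaluate(sp$train, sp$test, sel1, seed = 10L)
  r2 <- fitAndEvaluate(sp$train, testScrambled, sel1, seed = 10L)
  expect_equal(r1$trainMetrics@metrics, r2$trainMetrics@metrics)
  expect_identical(r1$hyperparameters, r2$hyperparameters)
})

test_that("the pipeline is reproducible under fixed seeds", {
  ft <- syntheticFeatureTable(5)
  a <- runRadiomicsPipeline(ft, seed = 7L)
  b <- runRadiomicsPipeline(ft, seed = 7L)
  expect_identical(a$selectedFeatures, b$selectedFeatures)
  expect_equal(a$testMetrics@metrics, b$testMetrics@metrics)
  expect_equal(a$nTrainRows, 72)
  expect_equal(a$nTestRows, 30)
})

test_that("patient-level aggregation majority-votes the augmented rows", {
  ft <- syntheticFeatureTable(6, effect = 8, nFeat = 6)
  r <- runRadiomicsPipeline(ft, seed = 8L, aggregate = "patient")
  total <- r$testMetrics@tp + r$testMetrics@fp + r$testMetrics@fn +
    r$testMetrics@tn
  expect_equal(total, 10)   # 10 test patients, not 30 rows
})
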