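#' Construct a cut-off rule
#'
#' @param parameter column name (e.g. "tbr_max").
#' @param cutoff numeric cut-off.
#' @param direction side predicting pseudoprogression: "le" (inclusive
#'   below, TBRmean/TBRmax), "ge" (inclusive above, TTP) or "gt" (strictly
#'   above, slope).
#' @return a [CutoffRule-class].
#' @export
cutoffRule <- function(parameter, cutoff, direction = c("le", "ge", "gt")) {
  new("CutoffRule", parameter = parameter, cutoff = cutoff,
      direction = match.arg(direction))
}

#' The study's published cut-off rules for the conventional parameters
#'
#' TBRmean <= 1.95, TBRmax <= 2.25, TTP >= 25 min, slope > 0.3 SUV/h (the
#' slope threshold behaves exclusively at the observed 0.3 values).
#'
#' @return named list of [CutoffRule-class].
#' @export
publishedRules <- function() {
  list(tbr_mean = cutoffRule("tbr_mean", 1.95, "le"),
       tbr_max = cutoffRule("tbr_max", 2.25, "le"),
       ttp_min = cutoffRule("ttp_min", 25, "ge"),
       slope_suv_h = cutoffRule("slope_suv_h", 0.3, "gt"))
}

applyRule <- function(records, rule) {
  x <- records[[rule@parameter]]
  if (is.null(x) || anyNA(x))
    stop("parameter ", rule@parameter, " missing for some records")
  switch(rule@direction,
         le = x <= rule@cutoff,
         ge = x >= rule@cutoff,
         gt = x > rule@cutoff)
}

#' Metrics from confusion counts
#'
#' @param tp,fp,fn,tn confusion counts (pseudoprogression positive).
#' @param auc optional area under the ROC curve.
#' @return a [ClassificationMetrics-class]; metrics with a zero
#'   denominator are NA (undefined).
#' @export
classificationMetrics <- function(tp, fp, fn, tn, auc = NA_real_) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  m <- c(sensitivity = rat(tp, tp + fn),
         specificity = rat(tn, tn + fp),
         ppv = rat(tp, tp + fp),
         npv = rat(tn, tn + fn),
         fnr = rat(fn, tp + fn),
         fpr = rat(fp, fp + tn),
         accuracy = rat(tp + tn, tp + fp + fn + tn),
         f1 = rat(2 * tp, 2 * tp + fp + fn),
         mcc = if (mccDen > 0) (tp * tn - fp * fn) / mccDen else NA_real_,
         auc = auc)
  new("ClassificationMetrics", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn), metrics = m)
}

#' Classify a cohort by a cut-off rule
#'
#' Applies the rule (pseudoprogression positive) and derives the full
#' confusion-based metric bundle; the AUC slot carries the rank-based AUC
#' of the underlying continuous parameter oriented by the rule direction.
#'
#' @param records data.frame with the parameter and a \code{diagnosis}
#'   column ("EP"/"PSP").
#' @param rule a [CutoffRule-class].
#' @return a [ClassificationMetrics-class].
#' @export
classifyByRule <- function(records, rule) {
  pred <- applyRule(records, rule)
  pos <- records$diagnosis == "PSP"
  classificationMetrics(tp = sum(pred & pos), fp = sum(pred & !pos),
                        fn = sum(!pred & pos), tn = sum(!pred & !pos),
                        auc = rocAUC(records, rule@parameter,
                                     rule@direction))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney U with half credit for ties, divided by
#' \code{n_pos * n_neg}: the probability that a random pseudoprogression
#' patient scores more "PSP-like" than a random progression patient. The
#' orientation follows the rule direction ("le" means low values indicate
#' pseudoprogression).
#'
#' @param records data.frame with the parameter and \code{diagnosis}.
#' @param parameter column name.
#' @param direction "le", "ge" or "gt".
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(records, parameter, direction = "le") {
  x <- records[[parameter]]
  pos <- records$diagnosis == "PSP"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  s <- if (direction == "le") -x else x
  r <- rank(s)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Optimal cut-off by the sensitivity-specificity product
#'
#' Candidate cut-offs are the midpoints of adjacent distinct observed
#' values; the returned cut-off maximizes sensitivity x specificity, with
#' ties broken toward the candidate with higher specificity and then the
#' smaller cut-off.
#'
#' @inheritParams rocAUC
#' @return a [CutoffRule-class] at the optimal cut-off.
#' @export
optimalCutoff <- function(records, parameter, direction = c("le", "ge", "gt")) {
  direction <- match.arg(direction)
  x <- records[[parameter]]
  pos <- records$diagnosis == "PSP"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  v <- sort(unique(x))
  if (length(v) < 2) stop("parameter is constant")
  cand <- (v[-1] + v[-length(v)]) / 2
  sens <- spec <- numeric(length(cand))
  for (k in seq_along(cand)) {
    rule <- cutoffRule(parameter, cand[k], direction)
    pred <- applyRule(records, rule)
    sens[k] <- mean(pred[pos])
    spec[k] <- mean(!pred[!pos])
  }
  prod <- sens * spec
  best <- which(prod >= max(prod) - 1e-12)
  best <- best[order(-spec[best], cand[best])][1]
  cutoffRule(parameter, cand[best], direction)
}

#' Combine cut-off rules with logical AND
#'
#' Predicts pseudoprogression only when every rule individually predicts
#' it; this can only raise specificity and lower sensitivity relative to
#' the constituents.
#'
#' @param records data.frame with all parameters and \code{diagnosis}.
#' @param rules list of [CutoffRule-class].
#' @return a [ClassificationMetrics-class] (AUC is NA: a conjunction has
#'   no underlying continuous score).
#' @export
combineRules <- function(records, rules) {
  stopifnot(length(rules) >= 1)
  pred <- Reduce(`&`, lapply(rules, function(r) applyRule(records, r)))
  pos <- records$diagnosis == "PSP"
  classificationMetrics(tp = sum(pred & pos), fp = sum(pred & !pos),
                        fn = sum(!pred & pos), tn = sum(!pred & !pos))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' @param tp,fp,fn,tn counts, or a [ClassificationMetrics-class] as the
#'   first argument.
#' @return two-sided p-value.
#' @export
fisherExactP <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is(tp, "ClassificationMetrics")) {
    m <- tp
    tab <- matrix(c(m@tp, m@fn, m@fp, m@tn), 2)
  } else {
    tab <- matrix(c(tp, fn, fp, tn), 2)
  }
  stats::fisher.test(tab)$p.value
}

#' Two-sided Mann-Whitney U test
#'
#' Exact when both groups have at most 8 observations and there are no
#' ties; otherwise the normal approximation with tie correction (no
#' continuity correction).
#'
#' @param x,y numeric samples for the two groups.
#' @return two-sided p-value.
#' @export
mannWhitneyP <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value)
}

#' Kaplan-Meier median survival
#'
#' Fits the product-limit estimator and returns the smallest time at which
#' the survival function drops to 0.5 or below (NA when it never does).
#'
#' @param time follow-up times (months), positive.
#' @param event logical, TRUE for an observed event (FALSE = censored).
#' @return median survival time.
#' @export
kmMedian <- function(time, event) {
  stopifnot(length(time) == length(event), any(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  below <- fit$surv <= 0.5 + 1e-12
  if (!any(below)) return(NA_real_)
  fit$time[which(below)[1]]
}

#' Log-rank test between two survival groups
#'
#' @param time,event as in [kmMedian()].
#' @param group factor-like with two levels.
#' @return two-sided p-value (chi-square, 1 df).
#' @export
logRankP <- function(time, event, group) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
}

#' Reproduce the conventional-parameter classification tables
#'
#' Recomputes, from a cohort table, the single-parameter classification
#' results (four parameters at the published cut-offs) and the seven
#' parameter combinations (logical AND at the single-parameter cut-offs),
#' each with the ten metrics and Fisher's exact p. Compares against the
#' published values after rounding to the published precision.
#'
#' @param records cohort data.frame ([loadCohortFixture()] by default).
#' @return list with data.frames \code{single} and \code{combined} (rows =
#'   metrics, columns = parameter/combination), the published counterparts
#'   \code{publishedSingle}/\code{publishedCombined}, and logical
#'   data.frames \code{matchSingle}/\code{matchCombined}.
#' @export
reproduceTables <- function(records = loadCohortFixture()) {
  rules <- publishedRules()
  metricsToColumn <- function(cm) {
    m <- cm@metrics
    c(round(100 * m[c("sensitivity", "specificity", "ppv", "npv", "fnr",
                      "fpr", "accuracy")]),
      f1 = round(m[["f1"]], 2), mcc = round(m[["mcc"]], 2),
      auc = if (is.na(m[["auc"]])) NA else round(m[["auc"]], 2),
      p_value = round(fisherExactP(cm), 3))
  }
  rowNames <- c("Sensitivity", "Specificity", "PPV", "NPV", "FNR", "FPR",
                "Accuracy", "F1", "MCC", "AUC", "p")
  single <- vapply(rules, function(r)
    metricsToColumn(classifyByRule(records, r)), numeric(11))
  rownames(single) <- rowNames
  combos <- list(
    "tbr_mean+tbr_max" = c("tbr_mean", "tbr_max"),
    "tbr_mean+ttp" = c("tbr_mean", "ttp_min"),
    "tbr_mean+slope" = c("tbr_mean", "slope_suv_h"),
    "tbr_max+ttp" = c("tbr_max", "ttp_min"),
    "tbr_max+slope" = c("tbr_max", "slope_suv_h"),
    "ttp+slope" = c("ttp_min", "slope_suv_h"),
    "tbr_mean+tbr_max+ttp" = c("tbr_mean", "tbr_max", "ttp_min"))
  combined <- vapply(combos, function(ps) {
    cm <- combineRules(records, rules[ps])
    metricsToColumn(cm)[-10]   # no AUC row for conjunctions
  }, numeric(10))
  rownames(combined) <- rowNames[-10]
  pub <- publishedTables()
  list(single = as.data.frame(single),
       combined = as.data.frame(combined),
       publishedSingle = pub$single,
       publishedCombined = pub$combined,
       matchSingle = as.data.frame(single == as.matrix(pub$single)),
       matchCombined = as.data.frame(combined == as.matrix(pub$combined)))
}

#' Published classification results of the conventional parameters
#'
#' The printed single-parameter and combination classification tables,
#' transcribed for comparison in [reproduceTables()].
#'
#' @return list of data.frames \code{single} (12 metric rows x 4
#'   parameters) and \code{combined} (11 rows x 7 combinations).
#' @export
publishedTables <- function() {
  single <- data.frame(
    tbr_mean = c(75, 61, 63, 73, 25, 39, 68, 0.69, 0.36, 0.73, 0.045),
    tbr_max = c(81, 67, 68, 80, 19, 33, 74, 0.74, 0.48, 0.79, 0.007),
    ttp_min = c(75, 44, 55, 67, 25, 56, 59, 0.63, 0.20, 0.61, 0.297),
    slope_suv_h = c(56, 61, 56, 61, 44, 39, 59, 0.56, 0.17, 0.55, 0.492),
    row.names = c("Sensitivity", "Specificity", "PPV", "NPV", "FNR", "FPR",
                  "Accuracy", "F1", "MCC", "AUC", "p"))
  combined <- data.frame(
    "tbr_mean+tbr_max" = c(75, 72, 71, 76, 25, 28, 74, 0.73, 0.47, 0.015),
    "tbr_mean+ttp" = c(69, 78, 73, 74, 31, 22, 74, 0.71, 0.47, 0.014),
    "tbr_mean+slope" = c(50, 78, 67, 64, 50, 22, 65, 0.57, 0.29, 0.151),
    "tbr_max+ttp" = c(69, 83, 79, 75, 31, 17, 76, 0.73, 0.53, 0.005),
    "tbr_max+slope" = c(50, 89, 80, 67, 50, 11, 71, 0.62, 0.43, 0.023),
    "ttp+slope" = c(56, 61, 56, 61, 44, 39, 59, 0.56, 0.17, 0.492),
    "tbr_mean+tbr_max+ttp" = c(69, 89, 85, 76, 31, 11, 79, 0.76, 0.59, 0.001),
    row.names = c("Sensitivity", "Specificity", "PPV", "NPV", "FNR", "FPR",
                  "Accuracy", "F1", "MCC", "p"),
    check.names = FALSE)
  list(single = single, combined = combined)
}
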