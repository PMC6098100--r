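#' Confusion-matrix statistics
#'
#' Counts tp/tn/fp/fn from paired 0/1 vectors. Derived rates are accessed
#' with [specificity()] (100 tn / (tn + fp)), [sensitivity()]
#' (100 tp / (tp + fn)) and [accuracy()]; all on the 0-100 percent scale,
#' reported to one decimal in printed output while raw fractions stay exact
#' internally.
#'
#' @param labels observed 0/1 vector.
#' @param preds predicted 0/1 vector of the same length.
#' @return a [ConfusionStats-class].
#' @examples
#' confusionStats(c(1, 1, 0, 0), c(1, 0, 0, 1))   # ac = 50
#' @export
confusionStats <- function(labels, preds) {
  if (length(labels) != length(preds))
    stop("labels and preds must have equal length")
  if (length(labels) == 0L) stop("empty input")
  if (!all(labels %in% c(0, 1)) || !all(preds %in% c(0, 1)))
    stop("labels and preds must be binary 0/1")
  new("ConfusionStats",
      tp = sum(labels == 1 & preds == 1),
      tn = sum(labels == 0 & preds == 0),
      fp = sum(labels == 0 & preds == 1),
      fn = sum(labels == 1 & preds == 0))
}

#' Build ConfusionStats from raw counts
#'
#' Convenience constructor for published confusion tables.
#'
#' @param tp,tn,fp,fn nonnegative counts.
#' @return a [ConfusionStats-class].
#' @export
confusionFromCounts <- function(tp, tn, fp, fn) {
  new("ConfusionStats", tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted half. Equivalent
#' to exhaustive pairwise concordance counting.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores (higher = more positive).
#' @return scalar in \[0, 1\].
#' @examples
#' auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))   # 0.75
#' @export
auroc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC is undefined when only one class is present")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier on train and test series
#'
#' Produces the confusion blocks and AUROC for both series. For a
#' [LinearNetNetModel-class] the score is the discriminant S with the
#' boundary at 0; for a fitted menu classifier supply `predictFun` and a
#' probability `threshold` (default 0.5). The positive class is the
#' meta-label `P_ann_Aij` when present, else the link label `Aij`.
#'
#' @param model a [LinearNetNetModel-class], or any fitted object when
#'   `predictFun` is given.
#' @param train,test data.frames with the feature and label columns.
#' @param predictFun optional `function(model, featureMatrix) -> scores`.
#' @param threshold score cut-point when `predictFun` is used.
#' @return a list of class `"netnetReport"` with `train`/`test`
#'   [ConfusionStats-class], `aurocTrain`, `aurocTest` and `positiveClass`.
#' @export
evaluateModel <- function(model, train, test, predictFun = NULL,
                          threshold = 0.5) {
  labCol <- if ("P_ann_Aij" %in% names(train)) "P_ann_Aij" else "Aij"
  series <- function(tbl) {
    y <- tbl[[labCol]]
    if (is.null(predictFun)) {
      s <- scoreRecords(model, tbl)
      pred <- as.integer(s >= 0)
    } else {
      s <- predictFun(model, as.matrix(tbl[, mtFeatureNames()]))
      pred <- as.integer(s >= threshold)
    }
    list(cm = confusionStats(y, pred), auc = auroc(y, s))
  }
  tr <- series(train); te <- series(test)
  structure(list(train = tr$cm, test = te$cm,
                 aurocTrain = tr$auc, aurocTest = te$auc,
                 positiveClass = if (labCol == "P_ann_Aij")
                   "topology classified the pair correctly (meta-label 1)"
                 else "link present (Aij = 1)"),
            class = "netnetReport")
}

#' @export
print.netnetReport <- function(x, ...) {
  cat("Net-Net evaluation report\n")
  cat("  positive class:", x$positiveClass, "\n")
  blk <- function(name, cm, auc) {
    cat(sprintf("  %s series: Sp = %.1f  Sn = %.1f  Ac = %.1f  AUROC = %.3f\n",
                name, specificity(cm), sensitivity(cm), accuracy(cm), auc))
    cat(sprintf("    tn = %d  fp = %d  fn = %d  tp = %d\n",
                as.integer(cm@tn), as.integer(cm@fp),
                as.integer(cm@fn), as.integer(cm@tp)))
  }
  blk("training", x$train, x$aurocTrain)
  blk("test", x$test, x$aurocTest)
  invisible(x)
}

#' Write a report as CSV
#'
#' One row per series with counts, Sp/Sn/Ac (1 decimal) and AUROC.
#'
#' @param report a `"netnetReport"` from [evaluateModel()].
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
writeReport <- function(report, path) {
  row <- function(name, cm, auc)
    data.frame(series = name, tn = cm@tn, fp = cm@fp, fn = cm@fn, tp = cm@tp,
               Sp = round(specificity(cm), 1), Sn = round(sensitivity(cm), 1),
               Ac = round(accuracy(cm), 1), AUROC = auc)
  out <- rbind(row("training", report$train, report$aurocTrain),
               row("test", report$test, report$aurocTest))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
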