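#' Confusion matrix of a binary classifier
#'
#' Cross-tabulates true labels against predictions with the higher-mileage
#' class as positive. `P = TP + FN` and `N = FP + TN` are the positive and
#' negative support.
#'
#' @param labels true labels (`"high"`/`"low"` or 1/0).
#' @param predictions predicted labels, same coding.
#' @param tp,fn,fp,tn alternatively, construct directly from counts.
#' @return An object of class `"confusion_matrix"`: list with `tp`, `fn`,
#'   `fp`, `tn`, `P`, `N`.
#' @examples
#' confusion_matrix(tp = 75, fn = 5, fp = 3, tn = 77)
#' @export
confusion_matrix <- function(labels = NULL, predictions = NULL,
                             tp = NULL, fn = NULL, fp = NULL, tn = NULL) {
  if (is.null(labels)) {
    counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
    if (length(counts) != 4L || any(!is.finite(counts)) || any(counts < 0))
      stop("tp, fn, fp, tn must all be nonnegative counts")
  } else {
    if (length(labels) != length(predictions))
      stop("labels and predictions differ in length")
    y <- encode_labels(labels)
    p <- encode_labels(predictions)
    counts <- c(tp = sum(y == 1 & p == 1), fn = sum(y == 1 & p == 0),
                fp = sum(y == 0 & p == 1), tn = sum(y == 0 & p == 0))
  }
  structure(list(tp = counts[["tp"]], fn = counts[["fn"]],
                 fp = counts[["fp"]], tn = counts[["tn"]],
                 P = counts[["tp"]] + counts[["fn"]],
                 N = counts[["fp"]] + counts[["tn"]]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("true +", "true -"),
                              c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' Classifier performance metrics from a confusion matrix
#'
#' Computes every standard confusion-matrix metric exactly as convention
#' defines them:
#' accuracy = (TP+TN)/(P+N); sensitivity (= recall = TPR) = TP/(TP+FN);
#' specificity = TN/(FP+TN); precision = TP/(TP+FP);
#' F1 = 2 precision recall / (precision + recall);
#' FPR = FP/(FP+TN); the closed-form AUC = (TPR - FPR + 1)/2 of the single
#' operating point (equivalently (sensitivity + specificity)/2); and
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' MCC with any zero marginal sum is undefined and returned as `NA` with a
#' warning rather than silently 0.
#'
#' @param cm a [confusion_matrix()].
#' @return List of class `"metric_report"` with elements `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`, `tpr`, `fpr`,
#'   `auc_formula`, `mcc`.
#' @examples
#' m <- classifier_metrics(confusion_matrix(tp = 75, fn = 5, fp = 3, tn = 77))
#' round(m$accuracy, 4); round(m$f1, 4); round(m$mcc, 4)
#' @export
classifier_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop("cm: not a confusion_matrix")
  if (cm$P == 0 || cm$N == 0)
    stop("rate metrics need at least one positive and one negative")
  tpr <- cm$tp / (cm$tp + cm$fn)
  fpr <- cm$fp / (cm$fp + cm$tn)
  precision <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  f1 <- if (is.na(precision) || precision + tpr == 0) NA_real_
        else 2 * precision * tpr / (precision + tpr)
  marg <- c(cm$tp + cm$fp, cm$tp + cm$fn, cm$tn + cm$fp, cm$tn + cm$fn)
  mcc <- if (any(marg == 0)) {
    warning("MCC undefined: a marginal sum of the confusion matrix is 0")
    NA_real_
  } else (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(prod(marg))
  structure(list(
    accuracy = (cm$tp + cm$tn) / (cm$P + cm$N),
    sensitivity = tpr,
    specificity = cm$tn / (cm$fp + cm$tn),
    precision = precision,
    f1 = f1,
    tpr = tpr,
    fpr = fpr,
    auc_formula = (tpr - fpr + 1) / 2,
    mcc = mcc), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", 100 * v)
  cat("accuracy    ", pct(x$accuracy), "\n",
      "sensitivity ", pct(x$sensitivity), "\n",
      "specificity ", pct(x$specificity), "\n",
      "precision   ", pct(x$precision), "\n",
      "F1          ", sprintf("%.4f", x$f1), "\n",
      "MCC         ", sprintf("%.4f", x$mcc), "\n",
      "AUC (TPR-FPR+1)/2 ", sprintf("%.4f", x$auc_formula), "\n", sep = "")
  invisible(x)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps a threshold over the unique scores (ties grouped), producing the
#' monotone (FPR, TPR) staircase from (0, 0) to (1, 1), and integrates it
#' with the trapezoid rule. The trapezoidal AUC equals the Mann-Whitney
#' probability that a random positive outscores a random negative (ties
#' counted half).
#'
#' @param labels true labels (`"high"`/`"low"` or 1/0).
#' @param scores numeric score per row, higher = more positive (e.g. the
#'   softmax probability of the positive class).
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(labels, scores) {
  y <- encode_labels(labels)
  if (length(y) != length(scores)) stop("labels/scores length mismatch")
  if (!all(is.finite(scores))) stop("scores: non-finite values")
  nP <- sum(y == 1); nN <- sum(y == 0)
  if (nP == 0 || nN == 0)
    stop("ROC needs at least one positive and one negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, cumsum(vapply(thr, function(t) sum(y == 1 & scores == t),
                            1)) / nP)
  fpr <- c(0, cumsum(vapply(thr, function(t) sum(y == 0 & scores == t),
                            1)) / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auc = auc)
}
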