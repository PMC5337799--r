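#' Confusion matrix for labour-vs-pregnancy classification
#'
#' Labour (label 2) is the positive class: `TP` counts labour samples
#' predicted labour, `FN` labour predicted pregnancy, `TN` pregnancy
#' predicted pregnancy, `FP` pregnancy predicted labour.
#'
#' @param truth True labels in `{1, 2}`.
#' @param pred Predicted labels in `{1, 2}`, same length.
#' @return An object of class `confusion_matrix`: named integer vector
#'   `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) stopf("`truth` and `pred` lengths differ")
  if (length(truth) < 1L) stopf("need at least one observation")
  if (!all(truth %in% c(1, 2)) || !all(pred %in% c(1, 2))) {
    stopf("labels must be 1 (pregnancy) or 2 (labour)")
  }
  cm <- c(TP = sum(truth == 2 & pred == 2),
          FP = sum(truth == 1 & pred == 2),
          TN = sum(truth == 1 & pred == 1),
          FN = sum(truth == 2 & pred == 1))
  structure(as.integer(cm), names = names(cm), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x["TP"], x["FN"], x["FP"], x["TN"]), nrow = 2, byrow = TRUE,
              dimnames = list(truth = c("labour", "pregnancy"),
                              predicted = c("labour", "pregnancy")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy (percent)
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, all scaled to percent.
#'
#' @param cm A [confusion()] matrix (or named vector with `TP`, `FP`,
#'   `TN`, `FN`).
#' @return Named numeric vector `sensitivity`, `specificity`,
#'   `accuracy`, in percent.
#' @examples
#' classification_metrics(confusion(rep(c(1, 2), each = 4),
#'                                  c(1, 1, 1, 2, 2, 2, 1, 2)))
#' @export
classification_metrics <- function(cm) {
  need <- c("TP", "FP", "TN", "FN")
  if (!all(need %in% names(cm))) stopf("`cm` must have TP, FP, TN, FN")
  tp <- as.numeric(cm["TP"]); fp <- as.numeric(cm["FP"])
  tn <- as.numeric(cm["TN"]); fn <- as.numeric(cm["FN"])
  if (tp + fn == 0) stopf("sensitivity undefined: no positive (labour) samples")
  if (tn + fp == 0) stopf("specificity undefined: no negative (pregnancy) samples")
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn))
}

#' ROC curve and AUC over classifier scores
#'
#' Sweeps a decision threshold over the unique scores (plus sentinels
#' beyond both extremes), predicting labour when `score >= threshold`.
#' Tied scores share one threshold, so the curve is well defined under
#' ties; the area is computed by the trapezoidal rule, which under this
#' construction equals the Mann-Whitney statistic (ties counted 1/2).
#'
#' @param truth True labels in `{1, 2}`; both classes must be present.
#' @param scores Numeric classifier scores (larger = more labour-like).
#' @return An object of class `roc_curve`: list with `thresholds`
#'   (decreasing), `fpr`, `tpr` (each starting at 0 and ending at 1)
#'   and `auc`.
#' @export
roc_curve <- function(truth, scores) {
  if (length(truth) != length(scores)) stopf("length mismatch")
  if (!all(truth %in% c(1, 2))) stopf("labels must be in {1, 2}")
  check_numeric_vector(scores, "scores")
  pos <- truth == 2
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) mean(scores[pos] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(scores[!pos] >= th), numeric(1))
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  thr <- c(Inf, thr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d threshold(s), AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}
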