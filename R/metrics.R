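## Evaluation: confusion counts, sensitivity/specificity and trapezoidal
## AUROC.  The positive class is afib throughout (disease detection).

#' Confusion-matrix counts
#'
#' @param truth,predicted equal-length label vectors in
#'   `{"norm", "afib"}`; afib is the positive class.
#' @return named integer vector `c(TP=, FN=, TN=, FP=)`.
#' @export
confusionCounts <- function(truth, predicted) {
  if (!length(truth) || length(truth) != length(predicted))
    stop_argument("truth and predicted must be non-empty and equal length")
  if (!all(c(truth, predicted) %in% c("norm", "afib")))
    stop_argument("labels must be 'norm' or 'afib'")
  c(TP = sum(truth == "afib" & predicted == "afib"),
    FN = sum(truth == "afib" & predicted == "norm"),
    TN = sum(truth == "norm" & predicted == "norm"),
    FP = sum(truth == "norm" & predicted == "afib"))
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity (true-positive rate) is `TP / (TP + FN)`; specificity
#' (true-negative rate) is `TN / (TN + FP)`.  A ratio with a zero
#' denominator is returned as `NA` (flagged undefined), never as 0.
#'
#' @param cm named counts as returned by [confusionCounts()].
#' @return named numeric `c(sensitivity=, specificity=)`.
#' @export
sensitivitySpecificity <- function(cm) {
  need <- c("TP", "FN", "TN", "FP")
  if (!all(need %in% names(cm)))
    stop_argument("cm must carry named counts TP, FN, TN, FP")
  if (any(cm[need] < 0)) stop_argument("confusion counts must be >= 0")
  sens <- if ((cm[["TP"]] + cm[["FN"]]) > 0)
    cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]) else NA_real_
  spec <- if ((cm[["TN"]] + cm[["FP"]]) > 0)
    cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Trapezoidal AUROC
#'
#' Sweeps all distinct score thresholds, traces the ROC curve and
#' accumulates the area with the trapezoidal rule
#' (sum of 0.5 * (TPR_i + TPR_(i+1)) * (FPR_(i+1) - FPR_i)).  Handling
#' ties through distinct thresholds makes the result equal to the
#' Mann-Whitney pairwise probability with half credit for tied scores.
#' Higher scores must indicate the positive (afib) class, so callers
#' scoring with the sigmoid output (high = normal) should pass
#' `1 - score` or flip the labels.
#'
#' @param scores per-sample numeric scores.
#' @param truth labels in `{"norm", "afib"}`; afib positive.
#' @return area under the ROC curve in \[0, 1\].
#' @examples
#' aurocTrapezoid(c(0.1, 0.4, 0.35, 0.8), c("norm", "norm", "afib", "afib"))
#' @export
aurocTrapezoid <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop_argument("scores and truth must have equal length")
  if (!all(truth %in% c("norm", "afib")))
    stop_argument("labels must be 'norm' or 'afib'")
  pos <- truth == "afib"
  if (!any(pos) || all(pos))
    stop_argument("AUROC needs both classes present")
  np <- sum(pos); nn <- sum(!pos)
  # descending distinct thresholds; prepend +Inf for the (0,0) corner
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / nn, numeric(1))
  sum(0.5 * (tpr[-length(tpr)] + tpr[-1]) * diff(fpr))
}

#' Evaluate record-level predictions
#'
#' Convenience wrapper assembling the standard report from truth labels,
#' predicted labels and per-record scores.
#'
#' @param truth true labels (`"norm"`/`"afib"`).
#' @param predicted predicted labels.
#' @param scores optional per-record scores oriented so that higher means
#'   more normal (the pipeline's sigmoid pooling); internally flipped for
#'   the afib-positive ROC.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `auroc`
#'   (NA without scores) and `confusion`.
#' @export
evaluatePredictions <- function(truth, predicted, scores = NULL) {
  cm <- confusionCounts(truth, predicted)
  ss <- sensitivitySpecificity(cm)
  auc <- if (is.null(scores)) NA_real_ else aurocTrapezoid(-scores, truth)
  list(accuracy = mean(truth == predicted),
       sensitivity = ss[["sensitivity"]],
       specificity = ss[["specificity"]],
       auroc = auc, confusion = cm)
}
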