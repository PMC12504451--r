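## Record-level decision making: per-segment scoring, the confidence-sum
## voting rule, and decision-boundary selection.

#' Confidence-sum voting over segment labels
#'
#' Sums the per-segment confidences per class (`S_norm`, `S_afib`) and
#' returns the class with the larger sum, so a single high-confidence
#' segment can overrule two low-confidence ones.  An exact tie returns
#' `"afib"` (favoring sensitivity to disease in a screening setting).
#' Applies to any segment count.
#'
#' @param labels per-segment labels, `"norm"`/`"afib"`.
#' @param confidences per-segment confidences in \[0, 1\].
#' @return list with `label` (the voted class) and `class_sums` (named
#'   numeric `c(norm=, afib=)`).
#' @examples
#' voteLabels(c("afib", "norm", "norm"), c(0.99, 0.40, 0.50))$label  # afib
#' @export
voteLabels <- function(labels, confidences) {
  if (length(labels) < 1L) stop_argument("vote needs at least one segment")
  if (length(labels) != length(confidences))
    stop_argument("labels and confidences must have equal length")
  if (!all(labels %in% c("norm", "afib")))
    stop_argument("labels must be 'norm' or 'afib'")
  if (any(!is.finite(confidences)) || any(confidences < 0 | confidences > 1))
    stop_argument("confidences must lie in [0, 1]")
  s_norm <- sum(confidences[labels == "norm"])
  s_afib <- sum(confidences[labels == "afib"])
  list(label = if (s_afib >= s_norm) "afib" else "norm",
       class_sums = c(norm = s_norm, afib = s_afib))
}

#' Segment-wise prediction with voting for one sample
#'
#' Runs the second and third pipeline layers on an already-harmonized
#' signal: cut into fixed windows (optionally R-peak-anchored), rasterize
#' each window, score each image with the model, label each segment by the
#' decision boundary (norm iff score >= threshold), map scores to
#' class confidences (the score itself for norm, one minus it for afib),
#' and vote.
#'
#' @param model a trained [CNNModel-class].
#' @param signal a harmonized [Signal-class] (samples within \[-1, 1\]).
#' @param threshold decision boundary in (0, 1), default 0.5.
#' @param seg_seconds segment duration (default 10 s).
#' @param anchor_rpeaks anchor the first window at the first detected R
#'   peak.  Default FALSE: the prediction path cuts successive windows
#'   from the start of the record, so a 30 s device recording yields
#'   exactly three 10 s fragments.  Beat-aligned anchoring is a
#'   training-data preparation option.
#' @param record_id identifier carried into the result.
#' @return a [PredictionResult-class].
#' @export
predictSample <- function(model, signal, threshold = 0.5,
                          seg_seconds = 10, anchor_rpeaks = FALSE,
                          record_id = "record") {
  if (!is(signal, "Signal")) stop_argument("signal must be a Signal")
  if (threshold <= 0 || threshold >= 1)
    stop_argument("threshold must lie strictly inside (0, 1)")
  win <- round(seg_seconds * signal@fs)
  if (length(signal@samples) < win)
    stop_argument("signal duration %.2f s shorter than one %g s segment",
                  duration(signal), seg_seconds)
  anchor <- NULL
  if (anchor_rpeaks && length(signal@samples) > win) {
    anchor <- tryCatch(detectRPeaks(signal), slecg_argument_error = function(e) NULL)
    # keep the anchor only if a full window still fits behind it
    if (!is.null(anchor) && length(anchor@indices) &&
        (length(signal@samples) - anchor@indices[1] + 1L) < win)
      anchor <- NULL
  }
  segs <- segmentSignal(signal, seg_seconds, anchor)
  imgs <- lapply(seq_along(segs@segments), function(k)
    rasterizeSegment(segs@segments[[k]],
                     width = model@config$input_shape[2],
                     height = model@config$input_shape[1],
                     meta = list(offset = segs@start_indices[k],
                                 record_id = record_id)))
  scores <- predictSegment(model, imgs)
  labels <- ifelse(scores >= threshold, "norm", "afib")
  conf <- ifelse(labels == "norm", scores, 1 - scores)
  v <- voteLabels(labels, conf)
  new("PredictionResult", labels = labels, confidences = as.numeric(conf),
      raw_scores = as.numeric(scores), threshold = threshold,
      final_label = v$label, class_sums = v$class_sums,
      record_id = record_id)
}

#' Decision-boundary sweep
#'
#' Evaluates classification accuracy over a grid of candidate thresholds
#' (predicting norm iff score >= t) and returns the most accurate one.
#' Ties are broken toward the threshold closest to 0.5 (extreme cutoffs
#' generalize poorly), then toward the smaller threshold.
#'
#' @param scores per-sample scores in \[0, 1\] (higher = more normal).
#' @param labels true labels, `"norm"`/`"afib"`.
#' @param grid candidate thresholds within (0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`.  Grid values are rounded to 10 decimal
#'   places so that accumulation noise from `seq()` cannot shift a
#'   boundary past a score it should include.
#' @return list with `best_threshold`, `best_accuracy` and `table`
#'   (data.frame of threshold and accuracy over the grid).
#' @export
sweepThreshold <- function(scores, labels,
                           grid = seq(0.05, 0.95, by = 0.05)) {
  if (!length(scores) || length(scores) != length(labels))
    stop_argument("scores and labels must be non-empty and equal length")
  if (!length(grid)) stop_argument("threshold grid must be non-empty")
  grid <- round(grid, 10)
  if (any(grid <= 0 | grid >= 1))
    stop_argument("grid thresholds must lie strictly inside (0, 1)")
  if (!all(labels %in% c("norm", "afib")))
    stop_argument("labels must be 'norm' or 'afib'")
  acc <- vapply(grid, function(t)
    mean(ifelse(scores >= t, "norm", "afib") == labels), numeric(1))
  ord <- order(-acc, abs(grid - 0.5), grid)
  best <- ord[1]
  list(best_threshold = grid[best], best_accuracy = acc[best],
       table = data.frame(threshold = grid, accuracy = acc))
}
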