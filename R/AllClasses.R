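## Core S4 containers for the pipeline.  Each class mirrors one stage of the
## processing chain: raw signal -> harmonized signal -> segments -> images ->
## per-segment scores -> voted record-level label.

VALID_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                 paste0("V", 1:6), "SL")

#' Single-lead ECG signal
#'
#' One lead's samples in millivolts together with its sampling rate, lead
#' name and a free-text provenance tag.
#'
#' @slot samples numeric vector of samples (mV); all finite, length >= 1.
#' @slot fs sampling rate in Hz (> 0).
#' @slot lead lead name: one of I, II, III, aVR, aVL, aVF, V1-V6, or "SL"
#'   for a generic single-lead device recording.
#' @slot source free-text provenance tag (file of origin, generator seed, ...).
#'
#' @seealso [Signal()], [ECGRecord-class]
#' @export
setClass("Signal", representation(
  samples = "numeric",
  fs      = "numeric",
  lead    = "character",
  source  = "character"
))

setValidity("Signal", function(object) {
  msg <- character()
  if (length(object@samples) < 1L) msg <- c(msg, "signal must contain at least one sample")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, sprintf("lead %s contains non-finite samples", object@lead))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@lead) != 1L || !(object@lead %in% VALID_LEADS))
    msg <- c(msg, sprintf("unknown lead name '%s'", object@lead))
  if (length(msg)) msg else TRUE
})

#' Construct a Signal
#'
#' @param samples numeric vector of samples in millivolts.
#' @param fs sampling rate (Hz).
#' @param lead lead name (case-insensitive; canonicalized on construction).
#' @param source provenance tag.
#' @return A [Signal-class] object.
#' @examples
#' sig <- Signal(sin(2 * pi * 1 * seq(0, 10, by = 0.01)), fs = 100, lead = "I")
#' duration(sig)
#' @export
Signal <- function(samples, fs, lead = "SL", source = "") {
  if (!all(is.finite(samples)))
    stop_data("lead %s contains non-finite samples", lead)
  new("Signal", samples = as.numeric(samples), fs = as.numeric(fs),
      lead = canonicalLead(lead), source = as.character(source))
}

canonicalLead <- function(lead) {
  hit <- match(tolower(lead), tolower(VALID_LEADS))
  if (is.na(hit)) stop_lookup(
    "unknown lead name '%s'; available: %s", lead,
    paste(VALID_LEADS, collapse = ", "))
  VALID_LEADS[hit]
}

#' Multi-lead ECG record
#'
#' An ordered list of [Signal-class] objects sharing one sampling rate and
#' sample count, a class label and a record identifier.
#'
#' @slot signals list of Signal objects with unique lead names.
#' @slot label class tag: "norm", "afib" or "unlabeled".
#' @slot record_id record identifier.
#' @export
setClass("ECGRecord", representation(
  signals   = "list",
  label     = "character",
  record_id = "character"
))

setValidity("ECGRecord", function(object) {
  msg <- character()
  if (length(object@signals) < 1L) msg <- c(msg, "record must hold at least one signal")
  if (!all(vapply(object@signals, is, logical(1), "Signal")))
    msg <- c(msg, "all record members must be Signal objects")
  else {
    fs  <- vapply(object@signals, function(s) s@fs, numeric(1))
    len <- vapply(object@signals, function(s) length(s@samples), numeric(1))
    if (length(unique(fs))  != 1L) msg <- c(msg, "all signals must share one sampling rate")
    if (length(unique(len)) != 1L) msg <- c(msg, "all signals must share one sample count")
    leads <- vapply(object@signals, function(s) s@lead, character(1))
    if (anyDuplicated(leads)) msg <- c(msg, "lead names must be unique")
  }
  if (!(object@label %in% c("norm", "afib", "unlabeled")))
    msg <- c(msg, "label must be 'norm', 'afib' or 'unlabeled'")
  if (length(msg)) msg else TRUE
})

#' Construct an ECGRecord
#'
#' @param signals a Signal or list of Signals sharing fs and length.
#' @param label "norm", "afib" or "unlabeled".
#' @param record_id identifier string.
#' @return An [ECGRecord-class] object.
#' @export
ECGRecord <- function(signals, label = "unlabeled", record_id = "record") {
  if (is(signals, "Signal")) signals <- list(signals)
  new("ECGRecord", signals = signals, label = label,
      record_id = as.character(record_id))
}

#' Fixed-duration segments of one signal
#'
#' Ordered, non-overlapping, equal-length windows cut from a harmonized
#' signal, each covering `seg_seconds` seconds.
#'
#' @slot segments list of numeric vectors, each of round(seg_seconds * fs)
#'   samples.
#' @slot seg_seconds window duration in seconds.
#' @slot fs sampling rate (Hz).
#' @slot start_indices 1-based sample offset of each window; strictly
#'   increasing.
#' @slot source_id identifier of the record the windows came from.
#' @export
setClass("SegmentSet", representation(
  segments      = "list",
  seg_seconds   = "numeric",
  fs            = "numeric",
  start_indices = "integer",
  source_id     = "character"
))

setValidity("SegmentSet", function(object) {
  msg <- character()
  n <- round(object@seg_seconds * object@fs)
  if (!all(vapply(object@segments, length, integer(1)) == n))
    msg <- c(msg, sprintf("every segment must hold exactly %d samples", n))
  si <- object@start_indices
  if (length(si) != length(object@segments))
    msg <- c(msg, "one start index per segment required")
  if (length(si) > 1L && any(diff(si) < n))
    msg <- c(msg, "segments must be non-overlapping and in order")
  if (length(msg)) msg else TRUE
})

#' Detected R-peak positions
#'
#' @slot indices strictly increasing 1-based sample positions of R peaks.
#' @slot fs sampling rate (Hz) of the signal the peaks were found in.
#' @export
setClass("RPeakList", representation(indices = "integer", fs = "numeric"))

setValidity("RPeakList", function(object) {
  if (length(object@indices) > 1L && any(diff(object@indices) <= 0L))
    "peak indices must be strictly increasing" else TRUE
})

#' 96x96 grayscale rendering of one segment
#'
#' @slot pixels height x width intensity matrix, values in \[0, 1\];
#'   1 = trace, 0 = background; row 1 is amplitude +1 (top).
#' @slot meta list with the source segment offset and record id.
#' @export
setClass("ImagePatch", representation(pixels = "matrix", meta = "list"))

setValidity("ImagePatch", function(object) {
  msg <- character()
  if (any(dim(object@pixels) < 8L))
    msg <- c(msg, "image must be at least 8x8")
  px <- object@pixels
  if (!all(is.finite(px)) || any(px < 0) || any(px > 1))
    msg <- c(msg, "pixel intensities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Record-level prediction with per-segment detail
#'
#' @slot labels per-segment class labels ("norm"/"afib").
#' @slot confidences per-segment confidences in \[0, 1\] (sigmoid score for
#'   norm-labeled segments, one minus it for afib-labeled ones).
#' @slot raw_scores per-segment sigmoid outputs.
#' @slot threshold decision boundary used for per-segment labels.
#' @slot final_label voted record-level label.
#' @slot class_sums named numeric: summed confidences S_norm and S_afib.
#' @slot record_id record identifier.
#' @export
setClass("PredictionResult", representation(
  labels      = "character",
  confidences = "numeric",
  raw_scores  = "numeric",
  threshold   = "numeric",
  final_label = "character",
  class_sums  = "numeric",
  record_id   = "character"
))

setValidity("PredictionResult", function(object) {
  msg <- character()
  k <- length(object@labels)
  if (length(object@confidences) != k || length(object@raw_scores) != k)
    msg <- c(msg, "labels, confidences and raw_scores must have equal length")
  if (any(object@confidences < 0 | object@confidences > 1))
    msg <- c(msg, "confidences must lie in [0, 1]")
  if (!(object@final_label %in% c("norm", "afib")))
    msg <- c(msg, "final label must be 'norm' or 'afib'")
  if (length(msg)) msg else TRUE
})

#' Compact 2-D CNN handle
#'
#' Holds the architecture description, the weight arrays, training history
#' and the random state used to initialize them.  Built by [buildModel()],
#' fitted by [trainModel()].
#'
#' @slot config architecture/optimizer configuration from [modelConfig()].
#' @slot weights named list of numeric weight arrays.
#' @slot history per-epoch data.frame of loss/accuracy (empty before
#'   training).
#' @slot trained logical flag.
#' @export
setClass("CNNModel", representation(
  config  = "list",
  weights = "list",
  history = "data.frame",
  trained = "logical"
))

## show methods ------------------------------------------------------------

setMethod("show", "Signal", function(object) {
  cat(sprintf("Signal: lead %s, %d samples @ %g Hz (%.2f s)%s\n",
              object@lead, length(object@samples), object@fs,
              length(object@samples) / object@fs,
              if (nzchar(object@source)) paste0(" [", object@source, "]") else ""))
})

setMethod("show", "ECGRecord", function(object) {
  leads <- vapply(object@signals, function(s) s@lead, character(1))
  cat(sprintf("ECGRecord '%s': %d lead(s) [%s], %d samples @ %g Hz, label %s\n",
              object@record_id, length(leads), paste(leads, collapse = ", "),
              length(object@signals[[1]]@samples), object@signals[[1]]@fs,
              object@label))
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet: %d segment(s) of %g s @ %g Hz from '%s', offsets %s\n",
              length(object@segments), object@seg_seconds, object@fs,
              object@source_id,
              paste(object@start_indices, collapse = "/")))
})

setMethod("show", "RPeakList", function(object) {
  cat(sprintf("RPeakList: %d peak(s) @ %g Hz\n",
              length(object@indices), object@fs))
})

setMethod("show", "ImagePatch", function(object) {
  cat(sprintf("ImagePatch: %dx%d, %.1f%% trace pixels\n",
              nrow(object@pixels), ncol(object@pixels),
              100 * mean(object@pixels > 0.5)))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf(
    "PredictionResult '%s': final label %s (S_norm=%.3f, S_afib=%.3f)\n",
    object@record_id, object@final_label,
    object@class_sums[["norm"]], object@class_sums[["afib"]]))
  cat(sprintf("  segments: %s\n",
              paste(sprintf("%s(%.2f)", object@labels, object@raw_scores),
                    collapse = " ")))
})

setMethod("show", "CNNModel", function(object) {
  rep <- countParameters(object)
  cat(sprintf("CNNModel: input %s, filters %s, dense %d; %d trainable parameters%s\n",
              paste(object@config$input_shape, collapse = "x"),
              paste(object@config$conv_filters, collapse = "/"),
              object@config$dense_units, rep$grand_total,
              if (object@trained) " (trained)" else " (untrained)"))
})
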