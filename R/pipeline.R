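## End-to-end pipeline: configuration, training-image preparation from
## records, and record classification (load -> denoise -> harmonize ->
## segment -> render -> score -> vote).

#' Pipeline configuration
#'
#' @param denoise logical; run wavelet denoising (default TRUE).
#' @param harmonize logical; run resample/normalize/polarity (default TRUE).
#' @param denoise_config a [denoiseConfig()].
#' @param harmonize_config a [harmonizeConfig()].
#' @param seg_seconds segment duration (default 10 s).
#' @param anchor_rpeaks anchor segmentation at the first detected R peak
#'   for records longer than one segment.  Default FALSE, so a 30 s
#'   recording splits into exactly three successive 10 s fragments; set
#'   TRUE when preparing beat-aligned training images from long clinical
#'   records (anchoring sacrifices the trailing partial window).
#' @param threshold decision boundary in (0, 1) (default 0.5).
#' @param lead lead to analyze for multi-lead records (default `"I"`,
#'   the lead whose morphology matches single-lead devices; single-lead
#'   records are used as-is).
#' @return a list of class `"pipeline_config"`.
#' @export
pipelineConfig <- function(denoise = TRUE, harmonize = TRUE,
                           denoise_config = denoiseConfig(),
                           harmonize_config = harmonizeConfig(),
                           seg_seconds = 10, anchor_rpeaks = FALSE,
                           threshold = 0.5, lead = "I") {
  if (threshold <= 0 || threshold >= 1)
    stop_config("threshold must lie strictly inside (0, 1)")
  structure(list(denoise = denoise, harmonize = harmonize,
                 denoise_config = denoise_config,
                 harmonize_config = harmonize_config,
                 seg_seconds = seg_seconds, anchor_rpeaks = anchor_rpeaks,
                 threshold = threshold, lead = lead),
            class = "pipeline_config")
}

.pipeline_signal <- function(record, config) {
  sig <- if (length(record@signals) == 1L) record@signals[[1]]
         else selectLead(record, config$lead)
  if (config$denoise)
    sig <- denoiseSignal(sig, config$denoise_config)
  if (config$harmonize)
    sig <- harmonizeSignal(sig, config$harmonize_config)
  sig
}

#' Prepare training images from labeled records
#'
#' Runs the preprocessing chain on each record and rasterizes every
#' resulting segment, labeling each image with its record's label.
#'
#' @param records list of [ECGRecord-class] objects or of [synthRecord()]
#'   outputs.
#' @param config a [pipelineConfig()].
#' @param width,height image resolution (default 96x96).
#' @return list with `images` (list of [ImagePatch-class]) and `labels`
#'   (character vector).
#' @export
recordsToImages <- function(records, config = pipelineConfig(),
                            width = 96L, height = 96L) {
  images <- list(); labels <- character()
  for (rec in records) {
    if (is.list(rec) && !is.null(rec$record)) rec <- rec$record
    sig <- .pipeline_signal(rec, config)
    anchor <- NULL
    if (config$anchor_rpeaks &&
        length(sig@samples) > round(config$seg_seconds * sig@fs)) {
      anchor <- tryCatch(detectRPeaks(sig),
                         slecg_argument_error = function(e) NULL)
      if (!is.null(anchor) && length(anchor@indices) &&
          (length(sig@samples) - anchor@indices[1] + 1L) <
            round(config$seg_seconds * sig@fs))
        anchor <- NULL
    }
    segs <- segmentSignal(sig, config$seg_seconds, anchor)
    for (k in seq_along(segs@segments)) {
      images[[length(images) + 1L]] <-
        rasterizeSegment(segs@segments[[k]], width = width, height = height,
                         meta = list(record_id = rec@record_id,
                                     offset = segs@start_indices[k]))
      labels <- c(labels, rec@label)
    }
  }
  list(images = images, labels = labels)
}

#' Classify one record end to end
#'
#' Loads the record if given a path, applies the configured denoising and
#' harmonization, segments, rasterizes, scores each segment with the
#' model and votes.  Any stage error propagates with its stage name.
#'
#' @param x an [ECGRecord-class] or a file path accepted by
#'   [loadRecord()].
#' @param model a trained [CNNModel-class].
#' @param config a [pipelineConfig()].
#' @param ... passed to [loadRecord()] when `x` is a path.
#' @return a [PredictionResult-class].
#' @examples
#' \dontrun{
#' res <- classifyRecord("sample.mat", model, pipelineConfig(), fs_hint = 300)
#' finalLabel(res)
#' }
#' @export
classifyRecord <- function(x, model, config = pipelineConfig(), ...) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must come from pipelineConfig()")
  if (!is(model, "CNNModel")) stop_config("a trained model is required")
  record <- if (is(x, "ECGRecord")) x else loadRecord(x, ...)
  sig <- .pipeline_signal(record, config)
  predictSample(model, sig, threshold = config$threshold,
                seg_seconds = config$seg_seconds,
                anchor_rpeaks = config$anchor_rpeaks,
                record_id = record@record_id)
}

#' Classification report row
#'
#' Flattens a [PredictionResult-class] into one data.frame row for
#' delimited reports: record id, per-segment scores (slash-separated),
#' voted label and class sums.
#'
#' @param result a [PredictionResult-class].
#' @return one-row data.frame.
#' @export
reportRow <- function(result) {
  if (!is(result, "PredictionResult"))
    stop_argument("result must be a PredictionResult")
  data.frame(
    record_id = result@record_id,
    n_segments = length(result@raw_scores),
    segment_scores = paste(sprintf("%.4f", result@raw_scores), collapse = "/"),
    segment_labels = paste(result@labels, collapse = "/"),
    s_norm = result@class_sums[["norm"]],
    s_afib = result@class_sums[["afib"]],
    final_label = result@final_label,
    mean_score = mean(result@raw_scores))
}
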