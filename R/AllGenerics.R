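## Accessor generics.  Slot access stays internal to the package; user code
## goes through these.

#' @describeIn Signal-class sample vector (mV)
#' @param object,x a package object
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
setMethod("samples", "Signal", function(object) object@samples)

#' @describeIn Signal-class sampling rate in Hz
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
setMethod("samplingRate", "Signal", function(object) object@fs)
setMethod("samplingRate", "SegmentSet", function(object) object@fs)
setMethod("samplingRate", "RPeakList", function(object) object@fs)
setMethod("samplingRate", "ECGRecord",
          function(object) object@signals[[1]]@fs)

#' @describeIn Signal-class lead name
#' @export
setGeneric("leadName", function(object) standardGeneric("leadName"))
setMethod("leadName", "Signal", function(object) object@lead)

#' @describeIn Signal-class duration in seconds
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
setMethod("duration", "Signal",
          function(object) length(object@samples) / object@fs)

#' @describeIn ECGRecord-class list of member signals
#' @export
setGeneric("signals", function(object) standardGeneric("signals"))
setMethod("signals", "ECGRecord", function(object) object@signals)

#' @describeIn ECGRecord-class lead names in record order
#' @export
setGeneric("leadNames", function(object) standardGeneric("leadNames"))
setMethod("leadNames", "ECGRecord", function(object)
  vapply(object@signals, function(s) s@lead, character(1)))

#' @describeIn ECGRecord-class class label
#' @export
setGeneric("recordLabel", function(object) standardGeneric("recordLabel"))
setMethod("recordLabel", "ECGRecord", function(object) object@label)

#' @describeIn ECGRecord-class record identifier
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))
setMethod("recordId", "ECGRecord", function(object) object@record_id)
setMethod("recordId", "PredictionResult", function(object) object@record_id)

#' @describeIn SegmentSet-class list of sample windows
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
setMethod("segments", "SegmentSet", function(object) object@segments)

#' @describeIn SegmentSet-class 1-based start offset of each window
#' @export
setGeneric("startIndices", function(object) standardGeneric("startIndices"))
setMethod("startIndices", "SegmentSet", function(object) object@start_indices)

#' @describeIn RPeakList-class 1-based R-peak sample positions
#' @export
setGeneric("peakIndices", function(object) standardGeneric("peakIndices"))
setMethod("peakIndices", "RPeakList", function(object) object@indices)

#' @describeIn ImagePatch-class intensity matrix in \[0,1\]
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
setMethod("pixels", "ImagePatch", function(object) object@pixels)

#' @describeIn PredictionResult-class voted record-level label
#' @export
setGeneric("finalLabel", function(object) standardGeneric("finalLabel"))
setMethod("finalLabel", "PredictionResult", function(object) object@final_label)

#' @describeIn PredictionResult-class per-segment labels
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))
setMethod("segmentLabels", "PredictionResult", function(object) object@labels)

#' @describeIn PredictionResult-class per-segment sigmoid scores
#' @export
setGeneric("segmentScores", function(object) standardGeneric("segmentScores"))
setMethod("segmentScores", "PredictionResult", function(object) object@raw_scores)

#' @describeIn PredictionResult-class summed class confidences (S_norm, S_afib)
#' @export
setGeneric("classSums", function(object) standardGeneric("classSums"))
setMethod("classSums", "PredictionResult", function(object) object@class_sums)

#' @describeIn CNNModel-class per-epoch training history
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))
setMethod("trainingHistory", "CNNModel", function(object) object@history)

#' @describeIn CNNModel-class architecture and optimizer configuration
#' @export
setGeneric("modelConfigOf", function(object) standardGeneric("modelConfigOf"))
setMethod("modelConfigOf", "CNNModel", function(object) object@config)
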