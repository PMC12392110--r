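#' @rdname LFPRecording-class
#' @param object an object.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname LFPRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname LFPRecording-class
#' @export
setGeneric("recordingId", function(object) standardGeneric("recordingId"))

#' @rdname LFPRecording-class
#' @export
setGeneric("recordingMeta", function(object) standardGeneric("recordingMeta"))

#' @rdname LabelSeries-class
#' @param object an object.
#' @export
setGeneric("labelValues", function(object) standardGeneric("labelValues"))

#' @rdname EventList-class
#' @param object an object.
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' @rdname EventList-class
#' @export
setGeneric("eventOnsets", function(object) standardGeneric("eventOnsets"))

#' @rdname EventList-class
#' @export
setGeneric("eventOffsets", function(object) standardGeneric("eventOffsets"))

#' @rdname EventList-class
#' @export
setGeneric("eventDurations", function(object) standardGeneric("eventDurations"))

#' @rdname SegmentBatch-class
#' @param object an object.
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
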