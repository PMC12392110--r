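#' Construct an LFPRecording
#'
#' @param samples numeric vector of field-potential values.
#' @param samplingRate sampling rate in Hz.
#' @param recordingId identifier string.
#' @param meta named list of metadata (`group`, `hemisphere`, `treatment`,
#'   `animal_id`, `slice_id`); missing keys are filled with neutral
#'   defaults (`"naive"`, `"none"`, `"ctrl"`, `"a0"`, `"s0"`).
#'
#' @return an [LFPRecording-class] object.
#' @examples
#' rec <- LFPRecording(sin(seq_len(2000) / 50), 2000, "demo")
#' samplingRate(rec)
#' @export
LFPRecording <- function(samples, samplingRate, recordingId = "rec",
                         meta = list()) {
  defaults <- list(group = "naive", hemisphere = "none", treatment = "ctrl",
                   animal_id = "a0", slice_id = "s0")
  meta <- utils::modifyList(defaults, as.list(meta))
  new("LFPRecording", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      recordingId = as.character(recordingId), meta = meta)
}

#' @rdname LFPRecording-class
#' @export
setMethod("samples", "LFPRecording", function(object) object@samples)

#' @rdname LFPRecording-class
#' @export
setMethod("samplingRate", "LFPRecording", function(object) object@samplingRate)

#' @rdname LabelSeries-class
#' @export
setMethod("samplingRate", "LabelSeries", function(object) object@samplingRate)

#' @rdname EventList-class
#' @export
setMethod("samplingRate", "EventList", function(object) object@samplingRate)

#' @rdname LFPRecording-class
#' @export
setMethod("recordingId", "LFPRecording", function(object) object@recordingId)

#' @rdname LFPRecording-class
#' @export
setMethod("recordingMeta", "LFPRecording", function(object) object@meta)

#' @rdname LFPRecording-class
#' @param x an `LFPRecording`.
#' @export
setMethod("length", "LFPRecording", function(x) length(x@samples))

setMethod("show", "LFPRecording", function(object) {
  cat(sprintf("LFPRecording '%s': %d samples at %g Hz (%.1f s)\n",
              object@recordingId, length(object@samples),
              object@samplingRate,
              length(object@samples) / object@samplingRate))
  m <- object@meta
  cat(sprintf("  group=%s hemisphere=%s treatment=%s animal=%s slice=%s\n",
              m$group, m$hemisphere, m$treatment, m$animal_id, m$slice_id))
})

#' Construct a LabelSeries
#'
#' @param labels vector coercible to integer 0/1.
#' @param samplingRate label rate in Hz.
#' @return a [LabelSeries-class] object.
#' @export
LabelSeries <- function(labels, samplingRate) {
  new("LabelSeries", labels = as.integer(labels),
      samplingRate = as.numeric(samplingRate))
}

#' @rdname LabelSeries-class
#' @export
setMethod("labelValues", "LabelSeries", function(object) object@labels)

#' @rdname LabelSeries-class
#' @param x a `LabelSeries`.
#' @export
setMethod("length", "LabelSeries", function(x) length(x@labels))

setMethod("show", "LabelSeries", function(object) {
  cat(sprintf("LabelSeries: %d samples at %g Hz, %.1f%% positive\n",
              length(object@labels), object@samplingRate,
              100 * mean(object@labels)))
})

#' Construct an EventList from 0-based half-open sample intervals
#'
#' @param onsets 0-based inclusive onset sample indices.
#' @param offsets exclusive offset sample indices (`offset > onset`).
#' @param samplingRate sampling rate in Hz the indices refer to.
#' @param totalWindowS analyzed window duration in seconds.
#' @return an [EventList-class] object.
#' @examples
#' ev <- eventList(c(0, 500), c(400, 900), 2000, 10)
#' eventDurations(ev)
#' @export
eventList <- function(onsets, offsets, samplingRate, totalWindowS) {
  stopifnot(length(onsets) == length(offsets))
  o <- order(onsets)
  onsets <- as.integer(onsets[o]); offsets <- as.integer(offsets[o])
  new("EventList",
      ranges = IRanges::IRanges(start = onsets + 1L, end = offsets),
      samplingRate = as.numeric(samplingRate),
      totalWindowS = as.numeric(totalWindowS))
}

#' @rdname EventList-class
#' @export
setMethod("nEvents", "EventList", function(object) length(object@ranges))

#' @rdname EventList-class
#' @param x an `EventList`.
#' @export
setMethod("length", "EventList", function(x) length(x@ranges))

#' @rdname EventList-class
#' @export
setMethod("eventOnsets", "EventList",
          function(object) IRanges::start(object@ranges) - 1L)

#' @rdname EventList-class
#' @export
setMethod("eventOffsets", "EventList",
          function(object) IRanges::end(object@ranges))

#' @rdname EventList-class
#' @export
setMethod("eventDurations", "EventList", function(object) {
  IRanges::width(object@ranges) / object@samplingRate
})

#' Analyzed window length of an EventList, in seconds
#' @param events an [EventList-class].
#' @return numeric scalar.
#' @export
totalWindowS <- function(events) events@totalWindowS

setMethod("show", "EventList", function(object) {
  cat(sprintf("EventList: %d events at %g Hz over %.1f s\n",
              length(object@ranges), object@samplingRate,
              object@totalWindowS))
  if (length(object@ranges) > 0) {
    d <- eventDurations(object)
    cat(sprintf("  durations: mean %.3f s, range [%.3f, %.3f] s\n",
                mean(d), min(d), max(d)))
  }
})

#' @rdname SegmentBatch-class
#' @export
setMethod("nSegments", "SegmentBatch", function(object) nrow(object@segments))

setMethod("show", "SegmentBatch", function(object) {
  cat(sprintf("SegmentBatch: %d segments of %g s at %g Hz (%d samples)\n",
              nrow(object@segments), object@windowS, object@samplingRate,
              ncol(object@segments)))
})

setMethod("show", "BinnedPSD", function(object) {
  cat(sprintf("BinnedPSD: %d bins of %g Hz, %s\n",
              length(object@binCenters), object@binWidth,
              if (isTRUE(object@normalized)) "normalized (sums to 1)"
              else "raw density units"))
})

setMethod("show", "BootstrapBand", function(object) {
  cat(sprintf("BootstrapBand: %d bins, %.0f%% level, %d resamples\n",
              length(object@binCenters), 100 * object@level,
              object@nResamples))
})

setMethod("show", "SLEDetector", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SLEDetector: %d blocks, %d channels, kernel %d, %s padding (%s)\n",
    cfg$n_blocks, cfg$channels, cfg$kernel_size, cfg$padding_mode,
    if (isTRUE(object@trained)) "trained" else "untrained"))
  cat(sprintf("  receptive field: %d samples (%.2f s at %g Hz); %d parameters\n",
              receptiveField(cfg), receptiveField(cfg) / cfg$input_rate_hz,
              cfg$input_rate_hz, nDetectorParameters(object)))
})

#' Bin centers of a BinnedPSD or BootstrapBand
#' @param x a [BinnedPSD-class] or [BootstrapBand-class].
#' @return numeric vector of bin-center frequencies (Hz).
#' @export
binCenters <- function(x) x@binCenters

#' Per-bin power of a BinnedPSD
#' @param x a [BinnedPSD-class].
#' @return numeric vector.
#' @export
binPower <- function(x) x@power

#' Bounds of a BootstrapBand
#' @param x a [BootstrapBand-class].
#' @return a data.frame with `bin_center`, `mean`, `lower`, `upper`.
#' @export
bandBounds <- function(x) {
  data.frame(bin_center = x@binCenters, mean = x@mean,
             lower = x@lower, upper = x@upper)
}
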