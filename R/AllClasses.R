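#' @import methods
#' @importFrom IRanges IRanges
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' LFPRecording: a single-channel local field potential trace
#'
#' Container for one LFP recording: the sampled signal, its sampling rate,
#' an identifier, and experimental metadata (group, hemisphere, treatment,
#' animal and slice identifiers) as used in slice electrophysiology.
#'
#' @slot samples numeric vector of field-potential values (arbitrary units).
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot recordingId character identifier.
#' @slot meta named list of metadata; recognised keys are `group`
#'   (`"naive"`, `"sham"`, `"glioma"`), `hemisphere` (`"ipsi"`, `"contra"`,
#'   `"none"`), `treatment` (`"ctrl"`, `"CNB60"`, `"CNB120"`), `animal_id`
#'   and `slice_id`.
#'
#' @seealso [LFPRecording()] for the constructor.
#' @export
setClass("LFPRecording",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    recordingId = "character",
    meta = "list"
  )
)

setValidity("LFPRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  if (length(object@samples) < 1L) {
    msg <- c(msg, "samples must have length >= 1")
  }
  if (anyNA(object@samples) || any(!is.finite(object@samples))) {
    msg <- c(msg, "all samples must be finite")
  }
  if (length(object@recordingId) != 1L || is.na(object@recordingId)) {
    msg <- c(msg, "recordingId must be a single string")
  }
  if (length(msg)) msg else TRUE
})

#' LabelSeries: per-sample binary SLE annotation
#'
#' A per-sample 0/1 label track aligned to a (typically 125-Hz) recording:
#' 1 marks samples inside a seizure-like event.
#'
#' @slot labels integer vector with values in `{0, 1}`.
#' @slot samplingRate label rate in Hz (default use: 125).
#'
#' @export
setClass("LabelSeries",
  representation(labels = "integer", samplingRate = "numeric")
)

setValidity("LabelSeries", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  if (anyNA(object@labels) || !all(object@labels %in% c(0L, 1L))) {
    msg <- c(msg, "labels must be 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' EventList: sorted, non-overlapping SLE intervals
#'
#' Events are half-open, 0-based sample-index intervals `[onset, offset)`
#' at a stated sampling rate, backed by an [IRanges::IRanges] (stored
#' 1-based closed internally). The total analyzed window length is carried
#' so that rates and fractions are well defined.
#'
#' @slot ranges an `IRanges`; `start = onset + 1`, `end = offset`.
#' @slot samplingRate sampling rate (Hz) the indices refer to.
#' @slot totalWindowS analyzed duration in seconds.
#'
#' @seealso [eventList()], [eventOnsets()], [eventDurations()].
#' @export
setClass("EventList",
  representation(
    ranges = "IRanges",
    samplingRate = "numeric",
    totalWindowS = "numeric"
  )
)

setValidity("EventList", function(object) {
  msg <- character()
  r <- object@ranges
  n <- length(r)
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number")
  }
  if (length(object@totalWindowS) != 1L || object@totalWindowS < 0) {
    msg <- c(msg, "totalWindowS must be a single non-negative number")
  }
  if (n > 0) {
    s <- IRanges::start(r); e <- IRanges::end(r)
    if (any(e < s)) msg <- c(msg, "all events must have positive width")
    if (is.unsorted(s, strictly = FALSE)) {
      msg <- c(msg, "events must be sorted by onset")
    }
    if (n > 1 && any(s[-1] <= e[-n])) {
      msg <- c(msg, "events must be pairwise non-overlapping")
    }
    if (any(s < 1)) msg <- c(msg, "onsets must be >= 0")
    nmax <- round(object@totalWindowS * object@samplingRate)
    if (length(msg) == 0 && any(e > nmax)) {
      msg <- c(msg, "events must lie within the analyzed window")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SegmentBatch: fixed-length training windows with per-sample targets
#'
#' Non-overlapping fixed-length windows (30 s at the label rate by default,
#' i.e. 3,750 samples) cut from one or more recordings, together with
#' aligned per-sample 0/1 targets and per-segment provenance.
#'
#' @slot segments numeric matrix, one segment per row.
#' @slot targets numeric matrix of the same dimension, values in `{0, 1}`.
#' @slot provenance data.frame with columns `recording_id` and
#'   `start_index` (0-based sample index of the segment start).
#' @slot samplingRate rate in Hz the segments are sampled at.
#' @slot windowS window length in seconds.
#'
#' @export
setClass("SegmentBatch",
  representation(
    segments = "matrix",
    targets = "matrix",
    provenance = "data.frame",
    samplingRate = "numeric",
    windowS = "numeric"
  )
)

setValidity("SegmentBatch", function(object) {
  msg <- character()
  L <- round(object@windowS * object@samplingRate)
  if (ncol(object@segments) != L && nrow(object@segments) > 0) {
    msg <- c(msg, sprintf("segments must have %d columns", L))
  }
  if (!identical(dim(object@segments), dim(object@targets))) {
    msg <- c(msg, "segments and targets must have identical dimensions")
  }
  if (nrow(object@provenance) != nrow(object@segments)) {
    msg <- c(msg, "provenance must have one row per segment")
  }
  if (length(msg)) msg else TRUE
})

#' BinnedPSD: 0.2-Hz-binned power spectral density over (0, 30] Hz
#'
#' @slot binCenters bin-center frequencies in Hz.
#' @slot power per-bin power (sums to 1 if `normalized`).
#' @slot normalized logical flag.
#' @slot binWidth bin width in Hz.
#'
#' @export
setClass("BinnedPSD",
  representation(
    binCenters = "numeric",
    power = "numeric",
    normalized = "logical",
    binWidth = "numeric"
  )
)

setValidity("BinnedPSD", function(object) {
  msg <- character()
  if (length(object@binCenters) != length(object@power)) {
    msg <- c(msg, "binCenters and power must have equal length")
  }
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (isTRUE(object@normalized) &&
      abs(sum(object@power) - 1) > 1e-9) {
    msg <- c(msg, "normalized PSD must sum to 1 (within 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' BootstrapBand: per-bin bootstrap confidence envelope for binned PSDs
#'
#' @slot binCenters bin-center frequencies in Hz.
#' @slot mean per-bin across-recording mean.
#' @slot lower,upper per-bin percentile bounds.
#' @slot level confidence level (default 0.95).
#' @slot nResamples number of bootstrap resamples.
#'
#' @export
setClass("BootstrapBand",
  representation(
    binCenters = "numeric",
    mean = "numeric",
    lower = "numeric",
    upper = "numeric",
    level = "numeric",
    nResamples = "integer"
  )
)

setValidity("BootstrapBand", function(object) {
  msg <- character()
  n <- length(object@binCenters)
  if (length(object@mean) != n || length(object@lower) != n ||
      length(object@upper) != n) {
    msg <- c(msg, "mean, lower, upper must match binCenters in length")
  }
  tol <- 1e-12
  if (any(object@lower > object@mean + tol) ||
      any(object@mean > object@upper + tol)) {
    msg <- c(msg, "lower <= mean <= upper must hold per bin")
  }
  if (length(msg)) msg else TRUE
})

#' SLEDetector: dilated-convolution per-sample SLE classifier
#'
#' Holds the network configuration, the weight list, and (after training)
#' the per-epoch history (loss, raw and corrected validation accuracy,
#' learning rate).
#'
#' @slot config detector configuration list, see [detectorConfig()].
#' @slot weights named list of weight matrices/vectors.
#' @slot trained logical.
#' @slot history data.frame of per-epoch training diagnostics.
#'
#' @export
setClass("SLEDetector",
  representation(
    config = "list",
    weights = "list",
    trained = "logical",
    history = "data.frameOrNULL"
  )
)
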