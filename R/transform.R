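#' Select a time window from a recording
#'
#' Returns the half-open time slice `[start_min, end_min)` of the
#' recording, preserving metadata. The default 40-min analysis window of
#' a disinhibition-model session is minutes 100 to 140.
#'
#' @param recording an [LFPRecording-class].
#' @param start_min window start in minutes (inclusive).
#' @param end_min window end in minutes (exclusive).
#' @return an [LFPRecording-class] covering the window.
#' @export
selectAnalysisWindow <- function(recording, start_min = 100,
                                 end_min = 140) {
  stopifnot(is(recording, "LFPRecording"))
  assertScalar(start_min, "start_min", nonneg = TRUE)
  assertScalar(end_min, "end_min", positive = TRUE)
  fs <- recording@samplingRate
  n <- length(recording@samples)
  i0 <- round(start_min * 60 * fs)
  i1 <- round(end_min * 60 * fs)
  if (start_min >= end_min || i1 > n) {
    stop("analysis window [", start_min, ", ", end_min,
         ") min outside the recording", call. = FALSE)
  }
  LFPRecording(recording@samples[(i0 + 1):i1], fs,
               recording@recordingId, recording@meta)
}

#' Downsample a recording with anti-aliasing
#'
#' Applies a zero-phase low-pass at 0.4 x the target rate, then decimates
#' (integer factors) or linearly interpolates onto the new sample grid
#' (non-integer factors). A pure tone below the new Nyquist frequency
#' survives with amplitude loss < 5%.
#'
#' @param recording an [LFPRecording-class].
#' @param target_rate_hz target rate in Hz (default 125); must not exceed
#'   the original rate.
#' @return an [LFPRecording-class] at the target rate with
#'   `floor(n * target / original)` samples.
#' @export
downsampleRecording <- function(recording, target_rate_hz = 125) {
  stopifnot(is(recording, "LFPRecording"))
  assertScalar(target_rate_hz, "target_rate_hz", positive = TRUE)
  fs <- recording@samplingRate
  if (target_rate_hz > fs) {
    stop("target rate exceeds the original sampling rate", call. = FALSE)
  }
  if (abs(target_rate_hz - fs) < 1e-12) return(recording)
  x <- fftLowpass(recording@samples, fs, 0.4 * target_rate_hz,
                  rolloff = 0.1 * target_rate_hz)
  n <- length(x)
  m <- floor(n * target_rate_hz / fs)
  ratio <- fs / target_rate_hz
  if (abs(ratio - round(ratio)) < 1e-9) {
    k <- as.integer(round(ratio))
    y <- x[(0:(m - 1)) * k + 1]
  } else {
    tOld <- (seq_len(n) - 1) / fs
    tNew <- (0:(m - 1)) / target_rate_hz
    y <- stats::approx(tOld, x, xout = tNew)$y
  }
  LFPRecording(y, target_rate_hz, recording@recordingId, recording@meta)
}

#' Cut a labeled recording into fixed-length training segments
#'
#' Tiles the recording with non-overlapping windows of `window_s` seconds
#' (30 s at 125 Hz gives 3,750-sample segments); a trailing remainder
#' shorter than the window is dropped. Per-sample labels stay aligned 1:1
#' and the provenance (recording id, 0-based start index) of each segment
#' is recorded.
#'
#' @param recording an [LFPRecording-class] (typically at the 125-Hz
#'   label rate).
#' @param labelSeries a [LabelSeries-class] of the same length and rate.
#' @param window_s window length in seconds (default 30).
#' @return a [SegmentBatch-class].
#' @export
segmentRecording <- function(recording, labelSeries, window_s = 30) {
  stopifnot(is(recording, "LFPRecording"), is(labelSeries, "LabelSeries"))
  if (length(labelSeries@labels) != length(recording@samples) ||
      abs(labelSeries@samplingRate - recording@samplingRate) > 1e-9) {
    stop("labels are not aligned to the recording (length or rate ",
         "mismatch)", call. = FALSE)
  }
  fs <- recording@samplingRate
  L <- as.integer(round(window_s * fs))
  n <- length(recording@samples)
  k <- n %/% L
  if (k == 0) {
    return(new("SegmentBatch",
               segments = matrix(numeric(0), 0, L),
               targets = matrix(numeric(0), 0, L),
               provenance = data.frame(recording_id = character(0),
                                       start_index = integer(0)),
               samplingRate = fs, windowS = window_s))
  }
  idx <- seq_len(k * L)
  seg <- matrix(recording@samples[idx], nrow = k, ncol = L, byrow = TRUE)
  tgt <- matrix(as.numeric(labelSeries@labels[idx]), nrow = k, ncol = L,
                byrow = TRUE)
  prov <- data.frame(recording_id = rep(recording@recordingId, k),
                     start_index = (seq_len(k) - 1L) * L,
                     stringsAsFactors = FALSE)
  new("SegmentBatch", segments = seg, targets = tgt, provenance = prov,
      samplingRate = fs, windowS = window_s)
}

#' Standardize a segment to zero mean and unit standard deviation
#'
#' Uses the population (divide-by-n) standard deviation. A constant
#' segment maps to all-zeros with a warning, so dead stretches do not
#' abort batch preparation.
#'
#' @param segment numeric vector of length >= 2.
#' @return standardized numeric vector.
#' @export
standardizeSegment <- function(segment) {
  if (length(segment) < 2L) {
    stop("segment must have length >= 2", call. = FALSE)
  }
  m <- mean(segment)
  s <- sqrt(mean((segment - m)^2))
  if (s == 0) {
    warning("constant segment standardized to all-zeros")
    return(rep(0, length(segment)))
  }
  (segment - m) / s
}

#' Standardize every segment of a SegmentBatch
#'
#' @param batch a [SegmentBatch-class].
#' @return the batch with each row standardized (see
#'   [standardizeSegment()]).
#' @export
standardizeBatch <- function(batch) {
  stopifnot(is(batch, "SegmentBatch"))
  if (nrow(batch@segments) == 0) return(batch)
  m <- rowMeans(batch@segments)
  cen <- batch@segments - m
  s <- sqrt(rowMeans(cen^2))
  zero <- s == 0
  if (any(zero)) {
    warning(sum(zero), " constant segment(s) standardized to all-zeros")
    s[zero] <- 1
  }
  batch@segments <- cen / s
  batch
}

#' Map an EventList onto a different sampling rate
#'
#' Converts event boundaries through time (seconds), rounding to the
#' nearest sample at the new rate and keeping every event at least one
#' sample wide.
#'
#' @param events an [EventList-class].
#' @param samplingRate new rate in Hz.
#' @return an [EventList-class] at the new rate.
#' @export
resampleEvents <- function(events, samplingRate) {
  stopifnot(is(events, "EventList"))
  k <- samplingRate / events@samplingRate
  on <- as.integer(round(eventOnsets(events) * k))
  off <- pmax(as.integer(round(eventOffsets(events) * k)), on + 1L)
  nmax <- as.integer(round(events@totalWindowS * samplingRate))
  off <- pmin(off, nmax)
  keep <- off > on
  eventList(on[keep], off[keep], samplingRate, events@totalWindowS)
}
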