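#' Post-processing configuration for predicted SLE labels
#'
#' The rule-based correction applied to the segmenter's output:
#' probabilities are binarized, events shorter than `min_duration_s` are
#' dropped (most are misidentified interictal events or noise), events
#' separated by less than `merge_gap_s` are regarded as one, and each
#' event's endpoint is snapped to its final interior extremum.
#'
#' @param binarize_threshold probability threshold (default 0.5; a
#'   probability equal to the threshold maps to 1).
#' @param min_duration_s events strictly shorter than this are removed
#'   (default 0.1 s).
#' @param merge_gap_s gaps strictly shorter than this are fused
#'   (default 0.2 s).
#' @param extremum_neighborhood neighborhood in samples for the strict
#'   extremum comparison (default 1 = immediate neighbors).
#' @return a list of class `PostprocessConfig`.
#' @export
postprocessConfig <- function(binarize_threshold = 0.5,
                              min_duration_s = 0.1, merge_gap_s = 0.2,
                              extremum_neighborhood = 1L) {
  if (binarize_threshold <= 0 || binarize_threshold >= 1) {
    stop("binarize_threshold must be in (0, 1)", call. = FALSE)
  }
  assertScalar(min_duration_s, "min_duration_s", positive = TRUE)
  assertScalar(merge_gap_s, "merge_gap_s", positive = TRUE)
  assertScalar(extremum_neighborhood, "extremum_neighborhood",
               positive = TRUE)
  cfg <- list(binarize_threshold = binarize_threshold,
              min_duration_s = min_duration_s, merge_gap_s = merge_gap_s,
              extremum_neighborhood = as.integer(extremum_neighborhood))
  class(cfg) <- "PostprocessConfig"
  cfg
}

#' Binarize a probability series into labels
#'
#' @param probabilities numeric vector in `[0, 1]`.
#' @param threshold label is 1 iff probability >= threshold.
#' @param samplingRate label rate in Hz for the returned series.
#' @return a [LabelSeries-class].
#' @export
binarizeProbabilities <- function(probabilities, threshold = 0.5,
                                  samplingRate = 125) {
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  LabelSeries(as.integer(probabilities >= threshold), samplingRate)
}

#' Convert between label series and event lists
#'
#' Maximal runs of 1s become half-open events; the operations are mutual
#' inverses.
#'
#' @param labelSeries a [LabelSeries-class].
#' @param events an [EventList-class].
#' @param length total number of samples of the label series to produce.
#' @return `labelsToEvents` returns an [EventList-class];
#'   `eventsToLabels` returns a [LabelSeries-class].
#' @export
labelsToEvents <- function(labelSeries) {
  stopifnot(is(labelSeries, "LabelSeries"))
  runs <- runsOfOnes(labelSeries@labels)
  eventList(runs[, "onset"], runs[, "offset"], labelSeries@samplingRate,
            length(labelSeries@labels) / labelSeries@samplingRate)
}

#' @rdname labelsToEvents
#' @export
eventsToLabels <- function(events, length) {
  stopifnot(is(events, "EventList"))
  lab <- integer(length)
  on <- eventOnsets(events); off <- eventOffsets(events)
  for (i in seq_along(on)) {
    lab[(on[i] + 1):min(off[i], length)] <- 1L
  }
  LabelSeries(lab, events@samplingRate)
}

#' Drop events shorter than a minimum duration
#'
#' Events with duration strictly below `min_duration_s` are removed
#' (an event of exactly the minimum is kept); order is preserved.
#'
#' @param events an [EventList-class].
#' @param min_duration_s threshold in seconds (default 0.1).
#' @return an [EventList-class].
#' @export
dropShortEvents <- function(events, min_duration_s = 0.1) {
  stopifnot(is(events, "EventList"))
  keep <- eventDurations(events) >= min_duration_s - 1e-12
  eventList(eventOnsets(events)[keep], eventOffsets(events)[keep],
            events@samplingRate, events@totalWindowS)
}

#' Merge events separated by small gaps
#'
#' Consecutive events whose gap is strictly shorter than `merge_gap_s`
#' are regarded as one spanning event; the rule is applied transitively
#' (a chain of close events collapses to one). A gap of exactly
#' `merge_gap_s` is not merged.
#'
#' @param events an [EventList-class].
#' @param merge_gap_s threshold in seconds (default 0.2).
#' @return an [EventList-class].
#' @export
mergeCloseEvents <- function(events, merge_gap_s = 0.2) {
  stopifnot(is(events, "EventList"))
  n <- length(events)
  if (n <= 1) return(events)
  on <- eventOnsets(events); off <- eventOffsets(events)
  gapN <- merge_gap_s * events@samplingRate
  mOn <- on[1]; mOff <- off[1]
  outOn <- integer(0); outOff <- integer(0)
  for (i in 2:n) {
    if (on[i] - mOff < gapN - 1e-9) {
      mOff <- max(mOff, off[i])
    } else {
      outOn <- c(outOn, mOn); outOff <- c(outOff, mOff)
      mOn <- on[i]; mOff <- off[i]
    }
  }
  outOn <- c(outOn, mOn); outOff <- c(outOff, mOff)
  eventList(outOn, outOff, events@samplingRate, events@totalWindowS)
}

# 0-based indices of strict local extrema of v within [from, to) (0-based
# half-open), comparing against the immediate +-nb neighbors inside the
# event only
strictExtremaWithin <- function(v, from, to, nb = 1L) {
  lo <- from + 1L; hi <- to              # 1-based inclusive range
  if (hi - lo + 1 < 2 * nb + 1) return(integer(0))
  inner <- (lo + nb):(hi - nb)
  isMax <- rep(TRUE, length(inner)); isMin <- rep(TRUE, length(inner))
  for (k in seq_len(nb)) {
    isMax <- isMax & v[inner] > v[inner - k] & v[inner] > v[inner + k]
    isMin <- isMin & v[inner] < v[inner - k] & v[inner] < v[inner + k]
  }
  inner[isMax | isMin] - 1L              # back to 0-based
}

#' Snap event endpoints to the final interior extremum
#'
#' Each event's offset is moved to one past the last strict local
#' extremum (minimum or maximum, strict against its immediate neighbors
#' within the event) of the signal inside the event. Onsets never move;
#' events without an interior extremum are unchanged.
#'
#' @param events an [EventList-class].
#' @param recording an [LFPRecording-class] at the same rate.
#' @param neighborhood samples each side for the strict comparison
#'   (default 1).
#' @return an [EventList-class].
#' @export
snapEventEnds <- function(events, recording, neighborhood = 1L) {
  stopifnot(is(events, "EventList"), is(recording, "LFPRecording"))
  v <- recording@samples
  on <- eventOnsets(events); off <- eventOffsets(events)
  for (i in seq_along(on)) {
    ex <- strictExtremaWithin(v, on[i], off[i], neighborhood)
    if (length(ex) > 0) off[i] <- max(ex) + 1L
  }
  eventList(on, off, events@samplingRate, events@totalWindowS)
}

#' Full rule-based correction of a probability series
#'
#' Applies, in order: binarize, run extraction, removal of events shorter
#' than 0.1 s, merging of events separated by less than 0.2 s, and
#' endpoint snapping to the final extremum.
#'
#' @param probabilities numeric vector in `[0, 1]`, one per sample.
#' @param recording the [LFPRecording-class] the probabilities annotate
#'   (same rate and length; used for snapping).
#' @param config a [postprocessConfig()].
#' @return an [EventList-class] of corrected events.
#' @export
correctEvents <- function(probabilities, recording,
                          config = postprocessConfig()) {
  stopifnot(is(recording, "LFPRecording"),
            inherits(config, "PostprocessConfig"))
  if (length(probabilities) != length(recording@samples)) {
    stop("probabilities and recording have different lengths",
         call. = FALSE)
  }
  lab <- binarizeProbabilities(probabilities, config$binarize_threshold,
                               recording@samplingRate)
  ev <- labelsToEvents(lab)
  ev <- dropShortEvents(ev, config$min_duration_s)
  ev <- mergeCloseEvents(ev, config$merge_gap_s)
  snapEventEnds(ev, recording, config$extremum_neighborhood)
}

#' Corrected per-sample accuracy
#'
#' Fraction of samples on which the corrected predicted labels agree
#' with the truth labels.
#'
#' @param predicted an [EventList-class] of corrected events.
#' @param truth a [LabelSeries-class] at the same rate.
#' @return fraction in `[0, 1]`.
#' @export
correctedAccuracy <- function(predicted, truth) {
  stopifnot(is(predicted, "EventList"), is(truth, "LabelSeries"))
  n <- length(truth@labels)
  nPred <- round(predicted@totalWindowS * predicted@samplingRate)
  if (abs(predicted@samplingRate - truth@samplingRate) > 1e-9 ||
      nPred != n) {
    stop("alignment error: predicted events and truth labels cover ",
         "different windows", call. = FALSE)
  }
  lab <- labelValues(eventsToLabels(predicted, n))
  mean(lab == truth@labels)
}
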