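#' Detect spike troughs inside events
#'
#' A sample is a spike trough iff it is strictly smaller than every other
#' sample within `window_s` before and after it (0.165 s by default).
#' Only troughs lying inside an event are returned. Detection runs at
#' the recording's own (acquisition) rate, where trough timing is most
#' precise. Note that with intra-SLE spikes recurring at ~10 Hz the
#' 0.165-s window exceeds the inter-spike spacing, so shallower
#' neighboring troughs within the window are suppressed by construction
#' of the rule. The first and last samples of the trace are never
#' troughs (no two-sided neighborhood exists there).
#'
#' @param recording an [LFPRecording-class].
#' @param events an [EventList-class] at the same rate.
#' @param window_s half-window in seconds (default 0.165).
#' @return a data.frame with columns `index` (0-based sample index of
#'   each trough) and `event` (owning event number).
#' @export
detectSpikes <- function(recording, events, window_s = 0.165) {
  stopifnot(is(recording, "LFPRecording"), is(events, "EventList"))
  assertScalar(window_s, "window_s", positive = TRUE)
  if (abs(recording@samplingRate - events@samplingRate) > 1e-9) {
    stop("recording and events must share a sampling rate", call. = FALSE)
  }
  v <- recording@samples
  n <- length(v)
  w <- as.integer(round(window_s * recording@samplingRate))
  # strict local minima (immediate neighbors) as cheap candidates: any
  # strict window minimum is in particular a strict local minimum
  inner <- 2:(n - 1)
  cand <- inner[v[inner] < v[inner - 1] & v[inner] < v[inner + 1]]
  on <- eventOnsets(events); off <- eventOffsets(events)
  idx <- integer(0); owner <- integer(0)
  for (i in seq_along(on)) {
    ci <- cand[cand > on[i] & cand <= off[i]]      # 1-based in (on, off]
    for (p in ci) {
      lo <- max(1L, p - w); hi <- min(n, p + w)
      win <- v[lo:hi]
      if (sum(win <= v[p]) == 1L) {                # only p itself
        idx <- c(idx, p - 1L)
        owner <- c(owner, i)
      }
    }
  }
  data.frame(index = idx, event = owner)
}

#' The four SLE metrics
#'
#' * `sleFraction`: proportion of the analyzed window occupied by SLEs.
#' * `sleRate`: events per minute.
#' * `meanSleDuration`: mean event duration in seconds (`NA` when there
#'   are no events -- missing, not zero).
#' * `spikeFrequency`: total spikes over total event time (pooled), in
#'   Hz (`NA` without events).
#'
#' @param events an [EventList-class].
#' @param spikes data.frame from [detectSpikes()].
#' @return a numeric scalar.
#' @export
sleFraction <- function(events) {
  stopifnot(is(events, "EventList"))
  if (events@totalWindowS <= 0) {
    stop("analyzed window must be positive", call. = FALSE)
  }
  sum(eventDurations(events)) / events@totalWindowS
}

#' @rdname sleFraction
#' @export
sleRate <- function(events) {
  stopifnot(is(events, "EventList"))
  if (events@totalWindowS <= 0) {
    stop("analyzed window must be positive", call. = FALSE)
  }
  length(events) / (events@totalWindowS / 60)
}

#' @rdname sleFraction
#' @export
meanSleDuration <- function(events) {
  stopifnot(is(events, "EventList"))
  if (length(events) == 0) return(NA_real_)
  mean(eventDurations(events))
}

#' @rdname sleFraction
#' @export
spikeFrequency <- function(spikes, events) {
  stopifnot(is(events, "EventList"))
  tot <- sum(eventDurations(events))
  if (length(events) == 0 || tot <= 0) return(NA_real_)
  nrow(spikes) / tot
}

#' Count pauses in seizure-like activity
#'
#' Number of maximal event-free intervals strictly longer than
#' `pause_min_s` (2 min by default). Leading and trailing event-free
#' stretches of the analyzed window count as gaps; a window without any
#' event is one single gap.
#'
#' @param events an [EventList-class].
#' @param pause_min_s threshold in seconds (default 120; strict ">").
#' @return integer pause count.
#' @export
detectPauses <- function(events, pause_min_s = 120) {
  stopifnot(is(events, "EventList"))
  fs <- events@samplingRate
  total <- round(events@totalWindowS * fs)
  bounds <- c(0, as.vector(rbind(eventOnsets(events),
                                 eventOffsets(events))), total)
  gaps <- bounds[seq(1, length(bounds), by = 2)]
  starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  gapLen <- (ends - starts) / fs
  sum(gapLen > pause_min_s)
}

#' Compute the SLE metric row for one recording
#'
#' @param recording an [LFPRecording-class] at the acquisition rate.
#' @param events an [EventList-class] at the same rate.
#' @param spike_window_s spike-detection half-window (default 0.165 s).
#' @return a one-row data.frame: identifiers and metadata, `analyzed_s`,
#'   `n_events`, `fraction`, `mean_duration_s`, `rate_per_min`,
#'   `spike_freq_hz`, `n_pauses`.
#' @export
computeSleMetrics <- function(recording, events, spike_window_s = 0.165) {
  stopifnot(is(recording, "LFPRecording"), is(events, "EventList"))
  spikes <- detectSpikes(recording, events, spike_window_s)
  m <- recording@meta
  data.frame(
    recording_id = recording@recordingId,
    group = m$group, hemisphere = m$hemisphere, treatment = m$treatment,
    animal_id = m$animal_id, slice_id = m$slice_id,
    analyzed_s = events@totalWindowS,
    n_events = length(events),
    fraction = sleFraction(events),
    mean_duration_s = meanSleDuration(events),
    rate_per_min = sleRate(events),
    spike_freq_hz = spikeFrequency(spikes, events),
    n_pauses = detectPauses(events),
    stringsAsFactors = FALSE)
}

#' Aggregate a slice-level metric table
#'
#' At `level = "slice"` the table is returned unchanged. At
#' `level = "animal"` all slices of one animal within one experimental
#' group (group x hemisphere x treatment) are merged by pooling events
#' and analyzed time, then recomputing the metrics: the fraction is the
#' time-weighted mean, the mean duration the event-count-weighted mean,
#' the rate the pooled count over pooled time, and the spike frequency
#' the event-time-weighted mean. The result is invariant to slice order.
#'
#' @param metrics data.frame from [computeSleMetrics()] rows.
#' @param level `"slice"` or `"animal"`.
#' @return a metric data.frame.
#' @export
aggregateMetrics <- function(metrics, level = c("slice", "animal")) {
  level <- match.arg(level)
  if (level == "slice") return(metrics)
  if (anyNA(metrics$animal_id) || any(!nzchar(metrics$animal_id))) {
    stop("metadata error: animal_id required for animal-level ",
         "aggregation", call. = FALSE)
  }
  key <- interaction(metrics$group, metrics$hemisphere,
                     metrics$treatment, metrics$animal_id, drop = TRUE)
  out <- lapply(split(metrics, key), function(d) {
    analyzed <- sum(d$analyzed_s)
    nEv <- sum(d$n_events)
    evTime <- sum(d$fraction * d$analyzed_s)
    spikeCount <- sum(ifelse(d$n_events > 0,
                             d$spike_freq_hz * d$mean_duration_s *
                               d$n_events, 0))
    data.frame(
      recording_id = paste(sort(d$recording_id), collapse = "+"),
      group = d$group[1], hemisphere = d$hemisphere[1],
      treatment = d$treatment[1], animal_id = d$animal_id[1],
      slice_id = NA_character_,
      analyzed_s = analyzed, n_events = nEv,
      fraction = evTime / analyzed,
      mean_duration_s = if (nEv > 0) evTime / nEv else NA_real_,
      rate_per_min = nEv / (analyzed / 60),
      spike_freq_hz = if (evTime > 0) spikeCount / evTime else NA_real_,
      n_pauses = sum(d$n_pauses),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
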