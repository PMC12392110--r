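#' Configuration for one simulated disinhibition-model LFP recording
#'
#' Defaults emulate the recording conditions of the disinhibition slice
#' model: a 40-min analysis window sampled at 2,000 Hz, band-limited to
#' 30 Hz, seizure-like events (SLEs) occurring at ~12/min as near-rhythmic
#' ~10-Hz trains of similar-morphology spikes, event durations of ~2 s
#' (never below the 0.2-s definitional minimum), inter-event gaps of at
#' least 0.1 s, occasional isolated interictal spikes, and optional 50-Hz
#' mains contamination.
#'
#' @param duration_s recording duration in seconds (default 2400 = 40 min).
#' @param sampling_rate_hz acquisition rate in Hz (default 2000).
#' @param sle_rate_per_min mean SLE rate in events/min (default 12).
#' @param sle_duration_mean_s mean SLE duration in seconds (default 2).
#' @param sle_duration_cv coefficient of variation of SLE duration
#'   (lognormal, truncated below at 0.2 s; default 0.5).
#' @param intra_sle_spike_hz spike recurrence frequency inside events in Hz
#'   (default 10).
#' @param spike_amplitude spike trough depth in signal units (default 8).
#' @param spike_amplitude_cv per-spike lognormal amplitude jitter
#'   (default 0.2).
#' @param isi_cv inter-spike-interval jitter (default 0.05), keeping events
#'   "almost rhythmic".
#' @param spike_width_s width of the spike waveform in seconds
#'   (default 0.08).
#' @param min_gap_s minimum inter-event gap in seconds (default 0.1;
#'   must be >= 0.1).
#' @param baseline_noise_sd standard deviation of the band-limited
#'   baseline noise (default 1).
#' @param lowpass_cutoff_hz acquisition low-pass cutoff in Hz (default 30).
#' @param interictal_rate_per_min rate of isolated interictal spikes
#'   outside events (default 2/min).
#' @param hum_50hz_amplitude amplitude of added 50-Hz mains hum
#'   (default 0; added after band-limiting so it survives the filter).
#' @param seed integer random seed.
#'
#' @return a validated configuration list of class `SimRecordingConfig`.
#' @seealso [simulateRecording()], [simCohortConfig()].
#' @export
simRecordingConfig <- function(duration_s = 2400,
                               sampling_rate_hz = 2000,
                               sle_rate_per_min = 12,
                               sle_duration_mean_s = 2,
                               sle_duration_cv = 0.5,
                               intra_sle_spike_hz = 10,
                               spike_amplitude = 8,
                               spike_amplitude_cv = 0.2,
                               isi_cv = 0.05,
                               spike_width_s = 0.08,
                               min_gap_s = 0.1,
                               baseline_noise_sd = 1,
                               lowpass_cutoff_hz = 30,
                               interictal_rate_per_min = 2,
                               hum_50hz_amplitude = 0,
                               seed = 1L) {
  assertScalar(duration_s, "duration_s", positive = TRUE)
  assertScalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  assertScalar(sle_rate_per_min, "sle_rate_per_min", nonneg = TRUE)
  assertScalar(sle_duration_mean_s, "sle_duration_mean_s", positive = TRUE)
  assertScalar(sle_duration_cv, "sle_duration_cv", nonneg = TRUE)
  assertScalar(intra_sle_spike_hz, "intra_sle_spike_hz", positive = TRUE)
  assertScalar(spike_amplitude, "spike_amplitude", nonneg = TRUE)
  assertScalar(spike_width_s, "spike_width_s", positive = TRUE)
  assertScalar(min_gap_s, "min_gap_s", nonneg = TRUE)
  assertScalar(baseline_noise_sd, "baseline_noise_sd", nonneg = TRUE)
  assertScalar(lowpass_cutoff_hz, "lowpass_cutoff_hz", positive = TRUE)
  assertScalar(interictal_rate_per_min, "interictal_rate_per_min",
               nonneg = TRUE)
  assertScalar(hum_50hz_amplitude, "hum_50hz_amplitude", nonneg = TRUE)
  if (min_gap_s < 0.1) {
    stop("min_gap_s must be >= 0.1 s (SLE definition)", call. = FALSE)
  }
  if (sle_rate_per_min > 0) {
    excess <- 60 / sle_rate_per_min - sle_duration_mean_s - min_gap_s
    if (excess <= 0) {
      stop("sle_rate_per_min too high for the configured mean duration: ",
           "mean cycle would leave no room for inter-event gaps",
           call. = FALSE)
    }
  }
  cfg <- list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
              sle_rate_per_min = sle_rate_per_min,
              sle_duration_mean_s = sle_duration_mean_s,
              sle_duration_cv = sle_duration_cv,
              intra_sle_spike_hz = intra_sle_spike_hz,
              spike_amplitude = spike_amplitude,
              spike_amplitude_cv = spike_amplitude_cv,
              isi_cv = isi_cv, spike_width_s = spike_width_s,
              min_gap_s = min_gap_s, baseline_noise_sd = baseline_noise_sd,
              lowpass_cutoff_hz = lowpass_cutoff_hz,
              interictal_rate_per_min = interictal_rate_per_min,
              hum_50hz_amplitude = hum_50hz_amplitude,
              seed = as.integer(seed))
  class(cfg) <- "SimRecordingConfig"
  cfg
}

#' Treatment effect as multipliers on the generative SLE distribution
#'
#' Encodes an anticonvulsant-like effect as multiplicative changes of mean
#' SLE duration, intra-SLE spike frequency, and SLE rate. The identity
#' element `(1, 1, 1)` leaves the generative distribution unchanged.
#'
#' @param duration_multiplier multiplier on mean SLE duration (> 0).
#' @param spike_freq_multiplier multiplier on intra-SLE spike frequency.
#' @param rate_multiplier multiplier on SLE rate.
#' @return a list of class `TreatmentEffect`.
#' @export
treatmentEffect <- function(duration_multiplier = 1,
                            spike_freq_multiplier = 1,
                            rate_multiplier = 1) {
  assertScalar(duration_multiplier, "duration_multiplier", positive = TRUE)
  assertScalar(spike_freq_multiplier, "spike_freq_multiplier",
               positive = TRUE)
  assertScalar(rate_multiplier, "rate_multiplier", positive = TRUE)
  eff <- list(duration_multiplier = duration_multiplier,
              spike_freq_multiplier = spike_freq_multiplier,
              rate_multiplier = rate_multiplier)
  class(eff) <- "TreatmentEffect"
  eff
}

#' Configuration for a simulated cohort of recordings
#'
#' @param groups named list mapping a group label (e.g. `"ctrl"`,
#'   `"CNB120"`) to a [treatmentEffect()].
#' @param animals_per_group number of animals per group.
#' @param slices_per_animal integer range `c(min, max)` of slices per
#'   animal (default 2-6; the number is drawn per animal).
#' @param base base [simRecordingConfig()] modified per group by its
#'   treatment multipliers.
#' @param seed cohort seed; per-recording seeds are derived by a
#'   counter-based splitting scheme that depends only on the (animal,
#'   slice) position, so groups differing only in treatment share
#'   noise realizations.
#' @return a list of class `SimCohortConfig`.
#' @export
simCohortConfig <- function(groups, animals_per_group = 3,
                            slices_per_animal = c(2, 6),
                            base = simRecordingConfig(), seed = 1L) {
  if (length(groups) < 1L) {
    stop("at least one group is required", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("'groups' must be a named list of TreatmentEffect", call. = FALSE)
  }
  for (g in groups) {
    if (!inherits(g, "TreatmentEffect")) {
      stop("every group must carry a TreatmentEffect", call. = FALSE)
    }
  }
  assertScalar(animals_per_group, "animals_per_group", positive = TRUE)
  if (length(slices_per_animal) != 2L ||
      slices_per_animal[1] > slices_per_animal[2] ||
      slices_per_animal[1] < 1) {
    stop("slices_per_animal must be a valid range c(min, max)",
         call. = FALSE)
  }
  cfg <- list(groups = groups,
              animals_per_group = as.integer(animals_per_group),
              slices_per_animal = as.integer(slices_per_animal),
              base = base, seed = as.integer(seed))
  class(cfg) <- "SimCohortConfig"
  cfg
}

#' Single-trough waveform kernel used to stamp spikes
#'
#' A zero-baseline snippet with a unique strict minimum of depth
#' `-amplitude` at its center: a Gaussian trough (sigma = width/6),
#' shifted and scaled so that the endpoints are exactly zero. Scaling the
#' width stretches the kernel in time without changing the trough depth.
#'
#' @param kind `"spike"` (default width 0.08 s) or `"interictal"`
#'   (default width 0.12 s).
#' @param amplitude trough depth in signal units (>= 0).
#' @param width_s kernel width in seconds; `NULL` uses the kind's default.
#' @param samplingRate sampling rate in Hz.
#' @return numeric vector of odd length with minimum `-amplitude` at its
#'   center and zeros at both ends.
#' @export
waveformKernel <- function(kind = c("spike", "interictal"), amplitude = 1,
                           width_s = NULL, samplingRate = 2000) {
  kind <- match.arg(kind)
  if (is.null(width_s)) {
    width_s <- if (kind == "spike") 0.08 else 0.12
  }
  assertScalar(width_s, "width_s", positive = TRUE)
  assertScalar(amplitude, "amplitude", nonneg = TRUE)
  assertScalar(samplingRate, "samplingRate", positive = TRUE)
  half <- max(1L, floor(width_s * samplingRate / 2))
  t <- (-half:half) / samplingRate
  shape <- exp(-0.5 * (t / (width_s / 6))^2)
  edge <- shape[1]
  -amplitude * (shape - edge) / (1 - edge)
}

# mean of a lognormal(meanlog, sdlog) truncated below at c
truncatedLognormalMean <- function(mean, cv, lower) {
  if (cv <= 0) return(max(mean, lower))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  p <- stats::pnorm((log(lower) - meanlog) / sdlog, lower.tail = FALSE)
  mean * stats::pnorm((meanlog + sdlog^2 - log(lower)) / sdlog) / p
}

#' Expected SLE count of the simulator's renewal process
#'
#' The simulator draws events from a renewal process: inter-event gap =
#' `min_gap_s` plus an exponential excess, event duration lognormal
#' truncated below at 0.2 s. The mean cycle length is chosen so that the
#' long-run event rate equals `sle_rate_per_min`; the expected count over
#' the window is `duration_s / mean_cycle`.
#'
#' @param config a [simRecordingConfig()].
#' @return expected number of events (numeric).
#' @export
expectedEventCount <- function(config) {
  stopifnot(inherits(config, "SimRecordingConfig"))
  if (config$sle_rate_per_min <= 0) return(0)
  edur <- truncatedLognormalMean(config$sle_duration_mean_s,
                                 config$sle_duration_cv, 0.2)
  excess <- 60 / config$sle_rate_per_min - config$sle_duration_mean_s -
    config$min_gap_s
  cycle <- config$min_gap_s + excess + edur
  config$duration_s / cycle
}

# draw ground-truth event intervals (sample indices, 0-based half-open)
drawEvents <- function(cfg, n) {
  fs <- cfg$sampling_rate_hz
  if (cfg$sle_rate_per_min <= 0) {
    return(cbind(onset = integer(0), offset = integer(0)))
  }
  excess <- 60 / cfg$sle_rate_per_min - cfg$sle_duration_mean_s -
    cfg$min_gap_s
  sdlog <- sqrt(log(1 + cfg$sle_duration_cv^2))
  meanlog <- log(cfg$sle_duration_mean_s) - sdlog^2 / 2
  minGapN <- as.integer(ceiling(cfg$min_gap_s * fs))
  minDurN <- as.integer(ceiling(0.2 * fs))
  onsets <- integer(0); offsets <- integer(0)
  pos <- 0L
  repeat {
    gap <- cfg$min_gap_s + stats::rexp(1, rate = 1 / excess)
    onset <- pos + max(as.integer(round(gap * fs)), minGapN)
    dur <- stats::rlnorm(1, meanlog, sdlog)
    while (dur < 0.2) dur <- stats::rlnorm(1, meanlog, sdlog)
    offset <- onset + max(as.integer(round(dur * fs)), minDurN)
    if (offset > n) break
    onsets <- c(onsets, onset); offsets <- c(offsets, offset)
    pos <- offset
  }
  cbind(onset = onsets, offset = offsets)
}

#' Simulate one LFP recording with ground-truth SLEs
#'
#' Assembles band-limited Gaussian baseline noise, SLEs stamped as
#' near-rhythmic trains of single-trough spike kernels, isolated
#' interictal spikes outside events, and optional 50-Hz hum. Ground-truth
#' events always satisfy the operational SLE definition (duration >=
#' 0.2 s, inter-event gap >= `min_gap_s`). The entire pre-hum signal is
#' passed through a zero-phase low-pass at `lowpass_cutoff_hz`, emulating
#' the acquisition chain. Identical `config` (including `seed`) yields
#' bit-identical output.
#'
#' @param config a [simRecordingConfig()].
#' @param recordingId identifier for the generated recording.
#' @param meta metadata list passed to [LFPRecording()].
#' @return a list with elements `recording` ([LFPRecording-class]) and
#'   `events` ([EventList-class] ground truth at the acquisition rate).
#' @examples
#' sim <- simulateRecording(simRecordingConfig(duration_s = 30, seed = 1))
#' nEvents(sim$events)
#' @export
simulateRecording <- function(config, recordingId = "sim", meta = list()) {
  stopifnot(inherits(config, "SimRecordingConfig"))
  cfg <- config
  fs <- cfg$sampling_rate_hz
  n <- as.integer(round(cfg$duration_s * fs))
  set.seed(cfg$seed)

  ev <- drawEvents(cfg, n)

  # spike troughs within each event
  halfW <- floor(cfg$spike_width_s * fs / 2)
  kernel <- waveformKernel("spike", amplitude = 1,
                           width_s = cfg$spike_width_s, samplingRate = fs)
  troughIdx <- integer(0); troughAmp <- numeric(0)
  if (nrow(ev) > 0) {
    isiSd <- sqrt(log(1 + cfg$isi_cv^2))
    ampSd <- sqrt(log(1 + cfg$spike_amplitude_cv^2))
    period <- fs / cfg$intra_sle_spike_hz
    for (i in seq_len(nrow(ev))) {
      span <- ev[i, "offset"] - ev[i, "onset"]
      nmax <- ceiling(span / period) + 2L
      isis <- period * stats::rlnorm(nmax, -isiSd^2 / 2, isiSd)
      pos <- ev[i, "onset"] + halfW + cumsum(c(0, isis))
      pos <- round(pos[pos + halfW <= ev[i, "offset"]])
      if (length(pos) == 0) pos <- ev[i, "onset"] + halfW
      amps <- cfg$spike_amplitude *
        stats::rlnorm(length(pos), -ampSd^2 / 2, ampSd)
      troughIdx <- c(troughIdx, pos)
      troughAmp <- c(troughAmp, amps)
    }
  }

  # isolated interictal spikes away from any event
  iiIdx <- integer(0); iiAmp <- numeric(0)
  nII <- stats::rpois(1, cfg$interictal_rate_per_min * cfg$duration_s / 60)
  if (nII > 0) {
    cand <- sort(as.integer(round(stats::runif(nII, halfW + 1, n - halfW))))
    if (nrow(ev) > 0) {
      margin <- as.integer(round(0.3 * fs))
      bad <- vapply(cand, function(p) {
        any(p >= ev[, "onset"] - margin & p < ev[, "offset"] + margin)
      }, logical(1))
      cand <- cand[!bad]
    }
    if (length(cand) > 0) {
      ampSd <- sqrt(log(1 + cfg$spike_amplitude_cv^2))
      iiIdx <- cand
      iiAmp <- cfg$spike_amplitude *
        stats::rlnorm(length(cand), -ampSd^2 / 2, ampSd)
    }
  }

  # baseline noise, pre-filter SD chosen so the band-limited SD is close
  # to baseline_noise_sd
  rolloff <- 3
  bandFrac <- min(1, (cfg$lowpass_cutoff_hz + rolloff / 2) / (fs / 2))
  x <- stats::rnorm(n, sd = cfg$baseline_noise_sd / sqrt(bandFrac))

  iiKernel <- waveformKernel("interictal", amplitude = 1,
                             samplingRate = fs)
  stampKernel <- function(x, idx, amp, k) {
    kh <- (length(k) - 1L) %/% 2L
    for (j in seq_along(idx)) {
      lo <- idx[j] - kh; hi <- idx[j] + kh
      if (lo >= 1L && hi <= n) {
        x[lo:hi] <- x[lo:hi] + amp[j] * k
      }
    }
    x
  }
  x <- stampKernel(x, troughIdx, troughAmp, kernel)
  x <- stampKernel(x, iiIdx, iiAmp, iiKernel)

  x <- fftLowpass(x, fs, cfg$lowpass_cutoff_hz, rolloff)

  if (cfg$hum_50hz_amplitude > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + cfg$hum_50hz_amplitude *
      sin(2 * pi * 50 * (seq_len(n) - 1) / fs + phase)
  }

  rec <- LFPRecording(x, fs, recordingId, meta)
  events <- eventList(ev[, "onset"], ev[, "offset"], fs, cfg$duration_s)
  list(recording = rec, events = events)
}

#' Simulate a cohort of recordings across treatment groups
#'
#' Applies each group's treatment multipliers to the base recording
#' configuration, then simulates `animals_per_group` animals with a
#' per-animal number of slices drawn from `slices_per_animal`. Every
#' recording carries `(group label, animal, slice)` metadata. Seeds are
#' derived from the cohort seed by a counter-based scheme keyed on the
#' (animal, slice) position only, so two groups differing only in their
#' treatment effect share noise realizations (and an identity effect
#' reproduces the control recordings exactly).
#'
#' @param config a [simCohortConfig()].
#' @return a list with elements `recordings` (list of
#'   [LFPRecording-class]), `events` (list of ground-truth
#'   [EventList-class]), and `manifest` (data.frame with `recording_id`,
#'   `label`, `animal_id`, `slice_id`, `seed`).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimCohortConfig"))
  base <- config$base
  recs <- list(); evs <- list(); man <- list()
  maxSlices <- config$slices_per_animal[2]
  for (g in seq_along(config$groups)) {
    label <- names(config$groups)[g]
    eff <- config$groups[[g]]
    for (a in seq_len(config$animals_per_group)) {
      # slice count per animal: identical across groups by construction
      set.seed(splitSeed(config$seed, 900000 + a))
      rng <- seq(config$slices_per_animal[1], config$slices_per_animal[2])
      nSlices <- if (length(rng) == 1) rng else sample(rng, 1)
      for (s in seq_len(nSlices)) {
        counter <- (a - 1L) * maxSlices + s
        recSeed <- splitSeed(config$seed, counter)
        cfg <- base
        cfg$sle_duration_mean_s <-
          base$sle_duration_mean_s * eff$duration_multiplier
        cfg$intra_sle_spike_hz <-
          base$intra_sle_spike_hz * eff$spike_freq_multiplier
        cfg$sle_rate_per_min <-
          base$sle_rate_per_min * eff$rate_multiplier
        cfg$seed <- recSeed
        cfg <- do.call(simRecordingConfig, cfg)
        rid <- sprintf("%s_a%d_s%d", label, a, s)
        meta <- list(treatment = label,
                     animal_id = sprintf("a%d", a),
                     slice_id = sprintf("s%d", s))
        sim <- simulateRecording(cfg, recordingId = rid, meta = meta)
        recs[[rid]] <- sim$recording
        evs[[rid]] <- sim$events
        man[[rid]] <- data.frame(recording_id = rid, label = label,
                                 animal_id = meta$animal_id,
                                 slice_id = meta$slice_id,
                                 seed = recSeed,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  list(recordings = recs, events = evs,
       manifest = do.call(rbind, c(man, list(make.row.names = FALSE))))
}
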