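#' Configuration of the dilated-convolution SLE segmenter
#'
#' A WaveNet-style stack of gated residual dilated 1-D convolutions with
#' skip connections and a sigmoid per-sample head. The defaults (10
#' blocks, kernel 2, dilations 1, 2, 4, ..., 512, 32 channels) give a
#' receptive field of 1,024 samples (~8.2 s at 125 Hz) and a model small
#' enough for rapid CPU (re)training. Segmentation is offline, so
#' symmetric (non-causal) padding is the default; `"causal"` restricts
#' each output to past context only.
#'
#' @param input_rate_hz label-rate input in Hz (default 125).
#' @param segment_s segment length in seconds (default 30).
#' @param n_blocks number of residual blocks (default 10).
#' @param kernel_size convolution kernel size; 2 is the supported value.
#' @param dilations integer dilation schedule, one per block (default
#'   `2^(0:(n_blocks-1))`).
#' @param channels number of channels (default 32).
#' @param padding_mode `"symmetric"` (default) or `"causal"`.
#' @return a validated list of class `DetectorConfig`.
#' @export
detectorConfig <- function(input_rate_hz = 125, segment_s = 30,
                           n_blocks = 10, kernel_size = 2,
                           dilations = NULL, channels = 32,
                           padding_mode = c("symmetric", "causal")) {
  padding_mode <- match.arg(padding_mode)
  assertScalar(input_rate_hz, "input_rate_hz", positive = TRUE)
  assertScalar(segment_s, "segment_s", positive = TRUE)
  assertScalar(n_blocks, "n_blocks", positive = TRUE)
  assertScalar(channels, "channels", positive = TRUE)
  if (kernel_size != 2) {
    stop("kernel_size 2 is the supported value", call. = FALSE)
  }
  if (is.null(dilations)) dilations <- 2^(0:(n_blocks - 1))
  if (length(dilations) != n_blocks || any(dilations < 1)) {
    stop("dilations must supply one positive value per block",
         call. = FALSE)
  }
  cfg <- list(input_rate_hz = input_rate_hz, segment_s = segment_s,
              n_blocks = as.integer(n_blocks),
              kernel_size = as.integer(kernel_size),
              dilations = as.integer(dilations),
              channels = as.integer(channels),
              padding_mode = padding_mode)
  class(cfg) <- "DetectorConfig"
  if (receptiveField(cfg) > segment_s * input_rate_hz) {
    stop("receptive field (", receptiveField(cfg),
         " samples) exceeds the segment length", call. = FALSE)
  }
  cfg
}

#' Receptive field of a detector configuration, in samples
#'
#' `1 + sum((kernel_size - 1) * dilations)` over the blocks.
#'
#' @param config a [detectorConfig()] (or the config list of a trained
#'   detector).
#' @return integer number of samples.
#' @export
receptiveField <- function(config) {
  as.integer(1 + sum((config$kernel_size - 1) * config$dilations))
}

#' Training configuration for the SLE segmenter
#'
#' @param epochs number of training epochs (default 100).
#' @param initial_learning_rate Adam learning rate (default 1e-3).
#' @param plateau_patience_epochs epochs without improvement of the
#'   corrected validation accuracy before the learning rate is divided
#'   (default 2; the division happens when the stall exceeds this).
#' @param lr_decay_factor factor the learning rate is divided by on a
#'   plateau (default 10).
#' @param batch_size minibatch size in segments (default 32).
#' @param seed seed controlling initialization-independent training
#'   randomness (shuffling).
#' @return a list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 100, initial_learning_rate = 1e-3,
                        plateau_patience_epochs = 2, lr_decay_factor = 10,
                        batch_size = 32, seed = 1L) {
  assertScalar(epochs, "epochs", positive = TRUE)
  assertScalar(initial_learning_rate, "initial_learning_rate",
               positive = TRUE)
  assertScalar(plateau_patience_epochs, "plateau_patience_epochs",
               positive = TRUE)
  if (lr_decay_factor <= 1) {
    stop("lr_decay_factor must be > 1", call. = FALSE)
  }
  assertScalar(batch_size, "batch_size", positive = TRUE)
  cfg <- list(epochs = as.integer(epochs),
              initial_learning_rate = initial_learning_rate,
              plateau_patience_epochs = as.integer(plateau_patience_epochs),
              lr_decay_factor = lr_decay_factor,
              batch_size = as.integer(batch_size), seed = as.integer(seed))
  class(cfg) <- "TrainConfig"
  cfg
}

#' Augmentation specification for training segments
#'
#' Training data are split into four equal categories: unchanged; a weak
#' ~50-Hz component mixed with Gaussian noise; one contiguous 5-s portion
#' per 30-s segment replaced by a burst of Gaussian noise; and random
#' sample points replaced by Gaussian draws. Augmentation never alters
#' the targets. Noise scales are in standardized signal units (the batch
#' is standardized before augmenting). The 50-Hz component is added at
#' the 125-Hz label rate, where it is representable (Nyquist 62.5 Hz).
#'
#' @param hum_amplitude amplitude of the 50-Hz component (default 0.2).
#' @param hum_noise_sd SD of the Gaussian noise mixed with the hum
#'   (default 0.1).
#' @param burst_s length of the replaced portion in seconds (default 5).
#' @param burst_sd SD of the replacement noise burst (default 1).
#' @param pointwise_fraction fraction of sample points replaced in the
#'   pointwise category (default 0.1).
#' @param pointwise_sd SD of the pointwise Gaussian replacement
#'   (default 1).
#' @return a list of class `AugmentationSpec`.
#' @export
augmentationSpec <- function(hum_amplitude = 0.2, hum_noise_sd = 0.1,
                             burst_s = 5, burst_sd = 1,
                             pointwise_fraction = 0.1, pointwise_sd = 1) {
  assertScalar(hum_amplitude, "hum_amplitude", nonneg = TRUE)
  assertScalar(hum_noise_sd, "hum_noise_sd", nonneg = TRUE)
  assertScalar(burst_s, "burst_s", positive = TRUE)
  assertScalar(burst_sd, "burst_sd", nonneg = TRUE)
  assertScalar(pointwise_fraction, "pointwise_fraction", nonneg = TRUE)
  assertScalar(pointwise_sd, "pointwise_sd", nonneg = TRUE)
  spec <- list(hum_amplitude = hum_amplitude, hum_noise_sd = hum_noise_sd,
               burst_s = burst_s, burst_sd = burst_sd,
               pointwise_fraction = pointwise_fraction,
               pointwise_sd = pointwise_sd)
  class(spec) <- "AugmentationSpec"
  spec
}

#' Build an untrained SLE segmenter
#'
#' @param config a [detectorConfig()].
#' @param seed initialization seed; identical seeds give identical
#'   initial weights.
#' @return an [SLEDetector-class].
#' @export
buildDetector <- function(config = detectorConfig(), seed = 1L) {
  stopifnot(inherits(config, "DetectorConfig"))
  weights <- initNetParams(config, seed)
  new("SLEDetector", config = unclass(config), weights = weights,
      trained = FALSE, history = NULL)
}

#' Number of trainable parameters of a detector
#' @param detector an [SLEDetector-class].
#' @return integer parameter count.
#' @export
nDetectorParameters <- function(detector) {
  sum(vapply(detector@weights, length, integer(1)))
}

#' Duplicate a segment batch with sign inversion
#'
#' Appends a copy of the batch with all sample values negated; targets
#' are unchanged. This teaches the model that SLE polarity is arbitrary.
#'
#' @param batch a [SegmentBatch-class].
#' @return a [SegmentBatch-class] of twice the size.
#' @export
duplicateWithInversion <- function(batch) {
  stopifnot(is(batch, "SegmentBatch"))
  if (nrow(batch@segments) == 0) return(batch)
  batch@segments <- rbind(batch@segments, -batch@segments)
  batch@targets <- rbind(batch@targets, batch@targets)
  batch@provenance <- rbind(batch@provenance, batch@provenance)
  rownames(batch@provenance) <- NULL
  batch
}

#' Augment a standardized segment batch
#'
#' Assigns segments to the four augmentation categories in exactly equal
#' quarters (remainders distributed deterministically to the earlier
#' categories after a seeded shuffle) and applies the corresponding
#' perturbation. Targets are untouched; the category of each segment is
#' recorded in the provenance column `augmentation`.
#'
#' @param batch a standardized [SegmentBatch-class].
#' @param spec an [augmentationSpec()].
#' @param seed seed for category assignment and noise.
#' @return the augmented [SegmentBatch-class].
#' @export
augmentSegments <- function(batch, spec = augmentationSpec(), seed = 1L) {
  stopifnot(is(batch, "SegmentBatch"), inherits(spec, "AugmentationSpec"))
  n <- nrow(batch@segments)
  if (n == 0) return(batch)
  L <- ncol(batch@segments)
  fs <- batch@samplingRate
  burstLen <- as.integer(round(spec$burst_s * fs))
  if (burstLen > L) {
    stop("segment shorter than the burst length", call. = FALSE)
  }
  set.seed(seed)
  ord <- sample.int(n)
  base <- n %/% 4L
  sizes <- base + as.integer(seq_len(4) <= n %% 4L)
  cats <- rep(c("unchanged", "hum50hz_plus_gaussian", "burst_replacement",
                "pointwise_gaussian_replacement"), times = sizes)
  category <- character(n)
  category[ord] <- cats
  tt <- (seq_len(L) - 1) / fs
  for (i in seq_len(n)) {
    ci <- category[i]
    if (ci == "hum50hz_plus_gaussian") {
      phase <- stats::runif(1, 0, 2 * pi)
      batch@segments[i, ] <- batch@segments[i, ] +
        spec$hum_amplitude * sin(2 * pi * 50 * tt + phase) +
        stats::rnorm(L, sd = spec$hum_noise_sd)
    } else if (ci == "burst_replacement") {
      start <- sample.int(L - burstLen + 1L, 1)
      idx <- start:(start + burstLen - 1L)
      batch@segments[i, idx] <- stats::rnorm(burstLen,
                                             sd = spec$burst_sd)
    } else if (ci == "pointwise_gaussian_replacement") {
      k <- max(1L, as.integer(round(spec$pointwise_fraction * L)))
      idx <- sample.int(L, k)
      batch@segments[i, idx] <- stats::rnorm(k, sd = spec$pointwise_sd)
    }
  }
  batch@provenance$augmentation <- category
  batch
}

#' Recording-exclusive train/validation split with balancing
#'
#' Assigns each recording wholly to the training or validation side,
#' choosing the assignment that best balances (i) the share of time
#' occupied by SLEs and (ii) the proportion of treated recordings
#' between the two sides. All assignments with the requested validation
#' count are enumerated when feasible; otherwise a seeded random search
#' is used. Deterministic under a fixed seed.
#'
#' @param info data.frame with columns `recording_id`, `duration_s`,
#'   `sle_s` (total SLE-occupied seconds), and logical `treated`.
#' @param val_fraction fraction of recordings on the validation side
#'   (default 0.2; at least one recording per side).
#' @param seed seed for the random search fallback.
#' @param max_exhaustive enumerate exhaustively when the number of
#'   candidate splits is at most this (default 20,000).
#' @return a list of class `SplitPlan` with `assignment` (named vector of
#'   `"train"`/`"validation"`) and `diagnostics` (per-side SLE share and
#'   treated share).
#' @export
splitTrainVal <- function(info, val_fraction = 0.2, seed = 1L,
                          max_exhaustive = 20000) {
  needed <- c("recording_id", "duration_s", "sle_s", "treated")
  if (!all(needed %in% names(info))) {
    stop("info must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(info)
  if (n < 2) {
    stop("at least 2 recordings are required for a recording-exclusive ",
         "split", call. = FALSE)
  }
  nVal <- min(n - 1L, max(1L, as.integer(round(n * val_fraction))))
  score <- function(valIdx) {
    tr <- setdiff(seq_len(n), valIdx)
    sleTr <- sum(info$sle_s[tr]) / sum(info$duration_s[tr])
    sleVa <- sum(info$sle_s[valIdx]) / sum(info$duration_s[valIdx])
    trtTr <- mean(info$treated[tr])
    trtVa <- mean(info$treated[valIdx])
    abs(sleTr - sleVa) + abs(trtTr - trtVa)
  }
  if (choose(n, nVal) <= max_exhaustive) {
    combs <- utils::combn(n, nVal)
    scores <- apply(combs, 2, score)
    valIdx <- combs[, which.min(scores)]
  } else {
    set.seed(seed)
    best <- NULL; bestScore <- Inf
    for (i in seq_len(2000)) {
      cand <- sample.int(n, nVal)
      s <- score(cand)
      if (s < bestScore) { bestScore <- s; best <- cand }
    }
    valIdx <- best
  }
  assignment <- rep("train", n)
  assignment[valIdx] <- "validation"
  names(assignment) <- info$recording_id
  tr <- setdiff(seq_len(n), valIdx)
  diagnostics <- data.frame(
    side = c("train", "validation"),
    sle_share = c(sum(info$sle_s[tr]) / sum(info$duration_s[tr]),
                  sum(info$sle_s[valIdx]) / sum(info$duration_s[valIdx])),
    treated_share = c(mean(info$treated[tr]), mean(info$treated[valIdx])))
  structure(list(assignment = assignment, diagnostics = diagnostics),
            class = "SplitPlan")
}

# reconstruct per-recording series (probabilities / signals / targets)
# from a batch in provenance order
batchByRecording <- function(batch) {
  ids <- unique(batch@provenance$recording_id)
  lapply(stats::setNames(ids, ids), function(id) {
    rows <- which(batch@provenance$recording_id == id)
    rows[order(batch@provenance$start_index[rows])]
  })
}

# corrected per-sample validation accuracy over the validation batch,
# reassembling each recording from its segments in order
correctedValAccuracy <- function(weights, cfg, valBatch, ppConfig,
                                 chunk = 16L) {
  probs <- predictBatchMatrix(weights, cfg, valBatch@segments, chunk)
  byRec <- batchByRecording(valBatch)
  agree <- 0; total <- 0
  fs <- valBatch@samplingRate
  for (rows in byRec) {
    p <- as.vector(t(probs[rows, , drop = FALSE]))
    sig <- as.vector(t(valBatch@segments[rows, , drop = FALSE]))
    truth <- as.vector(t(valBatch@targets[rows, , drop = FALSE]))
    rec <- LFPRecording(sig, fs, "val")
    ev <- correctEvents(p, rec, ppConfig)
    lab <- labelValues(eventsToLabels(ev, length(p)))
    agree <- agree + sum(lab == truth)
    total <- total + length(truth)
  }
  agree / total
}

predictBatchMatrix <- function(weights, cfg, segMatrix, chunk = 16L) {
  n <- nrow(segMatrix)
  out <- matrix(0, n, ncol(segMatrix))
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    fw <- netForward(weights, cfg, segMatrix[i:j, , drop = FALSE])
    out[i:j, ] <- matrix(as.vector(fw$p), j - i + 1L,
                         ncol(segMatrix), byrow = TRUE)
    i <- j + 1L
  }
  out
}

#' Train the SLE segmenter
#'
#' Minimizes mean binary cross-entropy with Adam. After every epoch the
#' corrected validation accuracy (per-sample agreement after the
#' rule-based post-processing, see [correctEvents()]) is evaluated; when
#' it fails to improve for more than `plateau_patience_epochs` epochs the
#' learning rate is divided by `lr_decay_factor`. The weights of the
#' best epoch (by corrected validation accuracy) are retained.
#'
#' @param detector an [SLEDetector-class] from [buildDetector()].
#' @param trainBatch,valBatch standardized [SegmentBatch-class] objects;
#'   their provenance must not share recordings.
#' @param config a [trainConfig()].
#' @param postprocess a [postprocessConfig()] used for the corrected
#'   accuracy.
#' @param verbose print one line per epoch.
#' @return the trained [SLEDetector-class]; `@history` holds per-epoch
#'   `loss`, `val_accuracy_raw`, `val_accuracy_corrected` and `lr`.
#' @export
trainDetector <- function(detector, trainBatch, valBatch,
                          config = trainConfig(),
                          postprocess = postprocessConfig(),
                          verbose = FALSE) {
  stopifnot(is(detector, "SLEDetector"), is(trainBatch, "SegmentBatch"),
            is(valBatch, "SegmentBatch"), inherits(config, "TrainConfig"))
  if (nrow(trainBatch@segments) == 0 || nrow(valBatch@segments) == 0) {
    stop("training error: empty train or validation batch", call. = FALSE)
  }
  overlap <- intersect(unique(trainBatch@provenance$recording_id),
                       unique(valBatch@provenance$recording_id))
  if (length(overlap) > 0) {
    stop("training error: recordings shared between train and ",
         "validation: ", paste(overlap, collapse = ", "), call. = FALSE)
  }
  cfg <- detector@config
  weights <- detector@weights
  state <- adamInit(weights)
  lr <- config$initial_learning_rate
  n <- nrow(trainBatch@segments)
  bs <- min(config$batch_size, n)
  bestAcc <- -Inf; bestWeights <- weights; sinceImprove <- 0L
  hist <- vector("list", config$epochs)
  set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    lossSum <- 0; lossN <- 0L
    for (start in seq(1L, n, by = bs)) {
      rows <- ord[start:min(start + bs - 1L, n)]
      lg <- netLossGrad(weights, cfg,
                        trainBatch@segments[rows, , drop = FALSE],
                        trainBatch@targets[rows, , drop = FALSE])
      upd <- adamStep(weights, lg$grads, state, lr)
      weights <- upd$params; state <- upd$state
      lossSum <- lossSum + lg$loss * length(rows)
      lossN <- lossN + length(rows)
    }
    valProbs <- predictBatchMatrix(weights, cfg, valBatch@segments)
    rawAcc <- mean((valProbs >= 0.5) == (valBatch@targets == 1))
    corrAcc <- correctedValAccuracy(weights, cfg, valBatch, postprocess)
    if (corrAcc > bestAcc) {
      bestAcc <- corrAcc; bestWeights <- weights; sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
      if (sinceImprove > config$plateau_patience_epochs) {
        lr <- lr / config$lr_decay_factor
        sinceImprove <- 0L
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, loss = lossSum / lossN,
                                val_accuracy_raw = rawAcc,
                                val_accuracy_corrected = corrAcc,
                                lr = lr)
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  val acc %.4f  corrected %.4f  lr %g",
        epoch, lossSum / lossN, rawAcc, corrAcc, lr))
    }
  }
  detector@weights <- bestWeights
  detector@trained <- TRUE
  detector@history <- do.call(rbind, hist)
  detector
}

#' Predict per-sample SLE probabilities for a recording
#'
#' The recording must already be at the detector's input rate. It is cut
#' into consecutive segments which are standardized exactly as during
#' training and processed in order; a trailing partial window is
#' standardized, zero-padded to the full window, predicted, and
#' truncated. Output: one probability per input sample.
#'
#' @param detector an [SLEDetector-class].
#' @param recording an [LFPRecording-class] at the detector input rate.
#' @param chunk number of segments per forward pass (memory knob).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predictProbabilities <- function(detector, recording, chunk = 16L) {
  stopifnot(is(detector, "SLEDetector"), is(recording, "LFPRecording"))
  cfg <- detector@config
  if (abs(recording@samplingRate - cfg$input_rate_hz) > 1e-6) {
    stop("rate error: recording is at ", recording@samplingRate,
         " Hz but the detector expects ", cfg$input_rate_hz,
         " Hz; downsample first", call. = FALSE)
  }
  L <- as.integer(round(cfg$segment_s * cfg$input_rate_hz))
  x <- recording@samples
  n <- length(x)
  nSeg <- ceiling(n / L)
  segs <- matrix(0, nSeg, L)
  for (i in seq_len(nSeg)) {
    lo <- (i - 1L) * L + 1L
    hi <- min(i * L, n)
    piece <- x[lo:hi]
    piece <- if (length(piece) >= 2 &&
                 sqrt(mean((piece - mean(piece))^2)) > 0) {
      standardizeSegment(piece)
    } else {
      rep(0, length(piece))
    }
    segs[i, seq_along(piece)] <- piece
  }
  probs <- predictBatchMatrix(detector@weights, cfg, segs, chunk)
  as.vector(t(probs))[seq_len(n)]
}

#' Save or load a detector as a portable JSON archive
#'
#' The archive embeds the configuration, the weights, and the training
#' history, all as plain JSON.
#'
#' @param detector an [SLEDetector-class].
#' @param path file path (conventionally `.json`).
#' @return `loadDetector` returns the [SLEDetector-class];
#'   `saveDetector` returns `path` invisibly.
#' @export
saveDetector <- function(detector, path) {
  stopifnot(is(detector, "SLEDetector"))
  payload <- list(
    config = detector@config,
    trained = detector@trained,
    weights = lapply(detector@weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), values = as.vector(w))
      else list(dim = NULL, values = as.vector(w))
    }),
    history = detector@history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname saveDetector
#' @export
loadDetector <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  weights <- lapply(payload$weights, function(w) {
    v <- as.numeric(w$values)
    if (!is.null(w$dim) && length(w$dim) == 2) {
      matrix(v, w$dim[1], w$dim[2])
    } else v
  })
  cfg <- payload$config
  cfg$dilations <- as.integer(cfg$dilations)
  hist <- payload$history
  if (is.null(hist) || (is.data.frame(hist) && nrow(hist) == 0)) {
    hist <- NULL
  }
  new("SLEDetector", config = cfg, weights = weights,
      trained = isTRUE(payload$trained), history = hist)
}
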