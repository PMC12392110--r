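test_that("the default architecture has the stated receptive field", {
  cfg <- detectorConfig()
  expect_identical(receptiveField(cfg), 1024L)
  expect_identical(cfg$dilations, as.integer(2^(0:9)))
  # receptive field beyond the segment is rejected
  expect_error(detectorConfig(n_blocks = 13), "receptive field")
  expect_error(detectorConfig(kernel_size = 3), "kernel_size")
})

test_that("building with the same seed gives identical initial weights", {
  a <- buildDetector(tinyDetectorConfig(), seed = 42)
  b <- buildDetector(tinyDetectorConfig(), seed = 42)
  expect_identical(a@weights, b@weights)
  c <- buildDetector(tinyDetectorConfig(), seed = 43)
  expect_false(identical(a@weights, c@weights))
})

test_that("the network maps a segment to same-length probabilities", {
  det <- buildDetector(detectorConfig(), seed = 1)
  x <- matrix(rnorm(3750), 1, 3750)
  p <- as.vector(sleseg:::netForward(det@weights, det@config, x)$p)
  expect_identical(length(p), 3750L)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("backpropagation matches numeric gradients", {
  cfg <- detectorConfig(input_rate_hz = 10, segment_s = 2, n_blocks = 3,
                        channels = 4, dilations = c(1, 2, 4))
  det <- buildDetector(cfg, seed = 7)
  set.seed(1)
  x <- matrix(rnorm(40), 2, 20)
  y <- matrix(rbinom(40, 1, 0.4), 2, 20)
  lg <- sleseg:::netLossGrad(det@weights, det@config, x, y)
  eps <- 1e-6
  for (nm in names(det@weights)) {
    w <- det@weights[[nm]]
    for (i in seq_len(min(length(w), 3))) {
      wp <- det@weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- det@weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (sleseg:::netLossGrad(wp, det@config, x, y)$loss -
                sleseg:::netLossGrad(wm, det@config, x, y)$loss) /
        (2 * eps)
      ana <- lg$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("loss wiring: perfect predictions score ~0, inverted score high", {
  y <- rbinom(200, 1, 0.5)
  pGood <- ifelse(y == 1, 1 - 1e-7, 1e-7)
  expect_lt(bceLoss(pGood, y), 1e-5)
  expect_gt(bceLoss(1 - pGood, y), 10)
})

test_that("sign-inversion duplication doubles the batch with negated copies", {
  b <- prepLabeledBatch(1, 60, "inv", sampling_rate_hz = 1000)
  n <- nSegments(b)
  d <- duplicateWithInversion(b)
  expect_identical(nSegments(d), 2L * n)
  expect_identical(d@segments[n + 1, ], -b@segments[1, ])
  expect_identical(d@targets[n + 2, ], b@targets[2, ])
  # composition: applying twice gives 4x with pairwise-negated halves
  d2 <- duplicateWithInversion(d)
  expect_identical(nSegments(d2), 4L * n)
  expect_identical(d2@segments[2 * n + 1, ], -d@segments[1, ])
})

test_that("augmentation assigns exact quarters and never touches targets", {
  n <- 1000
  L <- 30 * 125
  batch <- new("SegmentBatch",
               segments = matrix(0, n, L),
               targets = matrix(rbinom(n * L, 1, 0.3), n, L),
               provenance = data.frame(recording_id = rep("r", n),
                                       start_index = seq_len(n)),
               samplingRate = 125, windowS = 30)
  targetsBefore <- batch@targets
  aug <- augmentSegments(batch, augmentationSpec(), seed = 3)
  counts <- table(aug@provenance$augmentation)
  expect_identical(as.vector(counts[c("unchanged",
                                      "hum50hz_plus_gaussian",
                                      "burst_replacement",
                                      "pointwise_gaussian_replacement")]),
                   rep(250L, 4))
  expect_identical(aug@targets, targetsBefore)
  # unchanged category really is unchanged
  un <- which(aug@provenance$augmentation == "unchanged")
  expect_true(all(aug@segments[un, ] == 0))
  # burst category: exactly 5 s x 125 Hz = 625 contiguous samples replaced
  bu <- which(aug@provenance$augmentation == "burst_replacement")[1]
  changed <- which(aug@segments[bu, ] != 0)
  expect_identical(length(changed), 625L)
  expect_identical(max(changed) - min(changed) + 1L, 625L)
  # hum category: dominant frequency of the added component is ~50 Hz
  hu <- which(aug@provenance$augmentation == "hum50hz_plus_gaussian")[1]
  ps <- computePsd(LFPRecording(aug@segments[hu, ], 125, "hum"))
  expect_lt(abs(ps$frequency[which.max(ps$psd)] - 50), 1)
})

test_that("augmentation rejects segments shorter than the burst", {
  b <- new("SegmentBatch", segments = matrix(0, 4, 375),
           targets = matrix(0, 4, 375),
           provenance = data.frame(recording_id = rep("r", 4),
                                   start_index = 1:4),
           samplingRate = 125, windowS = 3)
  expect_error(augmentSegments(b, augmentationSpec()), "burst")
})

test_that("the train/val split is recording-exclusive and balanced", {
  info <- data.frame(recording_id = paste0("r", 1:10),
                     duration_s = rep(600, 10),
                     sle_s = rep(150, 10),
                     treated = rep(c(TRUE, FALSE), 5))
  plan <- splitTrainVal(info, val_fraction = 0.2, seed = 1)
  expect_identical(sum(plan$assignment == "validation"), 2L)
  expect_identical(sort(unique(plan$assignment)),
                   c("train", "validation"))
  d <- plan$diagnostics
  expect_lt(abs(d$treated_share[1] - d$treated_share[2]), 0.10 + 1e-9)
  expect_error(splitTrainVal(info[1, ]), "at least 2")
})

test_that("the exhaustive split matches an independent brute-force search", {
  set.seed(8)
  info <- data.frame(recording_id = paste0("r", 1:8),
                     duration_s = runif(8, 300, 900),
                     sle_s = runif(8, 30, 300),
                     treated = rbinom(8, 1, 0.5) == 1)
  plan <- splitTrainVal(info, val_fraction = 0.25, seed = 1)
  valIdx <- which(plan$assignment == "validation")
  scoreOf <- function(v) {
    tr <- setdiff(1:8, v)
    abs(sum(info$sle_s[tr]) / sum(info$duration_s[tr]) -
          sum(info$sle_s[v]) / sum(info$duration_s[v])) +
      abs(mean(info$treated[tr]) - mean(info$treated[v]))
  }
  best <- min(apply(utils::combn(8, length(valIdx)), 2, scoreOf))
  expect_equal(scoreOf(valIdx), best, tolerance = 1e-12)
})

test_that("training validates inputs and records a per-epoch history", {
  b1 <- prepLabeledBatch(1, 60, "t1", sampling_rate_hz = 1000)
  b2 <- prepLabeledBatch(2, 60, "t2", sampling_rate_hz = 1000)
  det <- buildDetector(tinyDetectorConfig(), seed = 1)
  empty <- new("SegmentBatch", segments = matrix(numeric(0), 0, 3750),
               targets = matrix(numeric(0), 0, 3750),
               provenance = data.frame(recording_id = character(0),
                                       start_index = integer(0)),
               samplingRate = 125, windowS = 30)
  expect_error(trainDetector(det, empty, b2), "empty")
  expect_error(trainDetector(det, b1, b1), "shared")
  fit <- trainDetector(det, b1, b2, trainConfig(epochs = 1, seed = 1))
  expect_identical(nrow(fit@history), 1L)
  expect_true(all(c("loss", "val_accuracy_raw", "val_accuracy_corrected",
                    "lr") %in% names(fit@history)))
  expect_true(fit@trained)
})

test_that("a stalled validation accuracy divides the learning rate by 10", {
  b1 <- prepLabeledBatch(1, 60, "t1", sampling_rate_hz = 1000)
  b2 <- prepLabeledBatch(2, 60, "t2", sampling_rate_hz = 1000)
  det <- buildDetector(tinyDetectorConfig(), seed = 1)
  # a vanishing learning rate freezes the model, so the corrected
  # accuracy improves once (first epoch) and then stalls
  fit <- trainDetector(det, b1, b2,
                       trainConfig(epochs = 4,
                                   initial_learning_rate = 1e-12,
                                   plateau_patience_epochs = 2, seed = 1))
  expect_equal(fit@history$lr, c(1e-12, 1e-12, 1e-12, 1e-13))
})

test_that("retraining with identical seeds reproduces the history", {
  b1 <- prepLabeledBatch(1, 60, "t1", sampling_rate_hz = 1000)
  b2 <- prepLabeledBatch(2, 60, "t2", sampling_rate_hz = 1000)
  f1 <- trainDetector(buildDetector(tinyDetectorConfig(), seed = 5),
                      b1, b2, trainConfig(epochs = 2, seed = 5))
  f2 <- trainDetector(buildDetector(tinyDetectorConfig(), seed = 5),
                      b1, b2, trainConfig(epochs = 2, seed = 5))
  expect_identical(f1@history, f2@history)
  expect_identical(f1@weights, f2@weights)
})

test_that("prediction covers every sample and requires the input rate", {
  det <- buildDetector(tinyDetectorConfig(), seed = 2)
  rec <- LFPRecording(rnorm(2400 * 125), 125, "p")
  p <- predictProbabilities(det, rec)
  expect_identical(length(p), 300000L)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(predictProbabilities(det, rec), p)
  # trailing partial window is padded then truncated
  rec45 <- LFPRecording(rnorm(45 * 125), 125, "p45")
  expect_identical(length(predictProbabilities(det, rec45)), 45L * 125L)
  raw <- LFPRecording(rnorm(1000), 2000, "raw")
  expect_error(predictProbabilities(det, raw), "rate error")
})

test_that("a saved detector archive reproduces its predictions", {
  det <- buildDetector(tinyDetectorConfig(), seed = 3)
  rec <- LFPRecording(rnorm(60 * 125), 125, "arch")
  path <- withr::local_tempfile(fileext = ".json")
  saveDetector(det, path)
  back <- loadDetector(path)
  expect_equal(predictProbabilities(back, rec),
               predictProbabilities(det, rec), tolerance = 1e-12)
  expect_identical(back@config$dilations, det@config$dilations)
})
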