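test_that("binarization uses the >= tie rule and checks its domain", {
  lab <- binarizeProbabilities(c(0.2, 0.7, 0.9), 0.5, 125)
  expect_identical(labelValues(lab), c(0L, 1L, 1L))
  expect_identical(labelValues(binarizeProbabilities(0.5, 0.5, 125)), 1L)
  expect_identical(labelValues(binarizeProbabilities(c(0.1, 0.4), 0.5,
                                                     125)), c(0L, 0L))
  expect_error(binarizeProbabilities(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("labels and events are mutual inverses", {
  lab <- LabelSeries(c(0L, 1L, 1L, 0L, 1L), 125)
  ev <- labelsToEvents(lab)
  expect_identical(eventOnsets(ev), c(1L, 4L))
  expect_identical(eventOffsets(ev), c(3L, 5L))
  expect_identical(nEvents(labelsToEvents(LabelSeries(rep(0L, 10), 125))),
                   0L)
  set.seed(20)
  for (i in 1:50) {
    x <- as.integer(rbinom(sample(5:200, 1), 1, runif(1)))
    ls <- LabelSeries(x, 125)
    expect_identical(labelValues(eventsToLabels(labelsToEvents(ls),
                                                length(x))), x)
  }
})

test_that("short events are dropped with a strict boundary at 0.1 s", {
  ev <- eventList(c(0, 100), c(6, 163), 125, 10)  # 0.048 s and 0.504 s
  out <- dropShortEvents(ev)
  expect_identical(nEvents(out), 1L)
  expect_identical(eventOnsets(out), 100L)
  # duration exactly 0.1 s is kept (strict "<"); one sample less is not
  evB <- eventList(0, 100, 1000, 10)
  expect_identical(nEvents(dropShortEvents(evB)), 1L)
  evC <- eventList(0, 99, 1000, 10)
  expect_identical(nEvents(dropShortEvents(evC)), 0L)
  expect_identical(nEvents(dropShortEvents(
    eventList(integer(0), integer(0), 125, 10))), 0L)
  # idempotence
  expect_identical(eventOnsets(dropShortEvents(dropShortEvents(ev))),
                   eventOnsets(out))
})

test_that("close events merge transitively with a strict 0.2-s boundary", {
  fs <- 1000
  ev <- eventList(c(0, 650), c(500, 1200), fs, 10)     # gap 0.15 s
  out <- mergeCloseEvents(ev)
  expect_identical(nEvents(out), 1L)
  expect_identical(eventOnsets(out), 0L)
  expect_identical(eventOffsets(out), 1200L)
  # gap exactly 0.2 s stays separate
  ev2 <- eventList(c(0, 700), c(500, 1200), fs, 10)
  expect_identical(nEvents(mergeCloseEvents(ev2)), 2L)
  # chain of three events with 0.1-s gaps collapses to one
  ev3 <- eventList(c(0, 600, 1200), c(500, 1100, 1700), fs, 10)
  expect_identical(nEvents(mergeCloseEvents(ev3)), 1L)
  # idempotence
  m <- mergeCloseEvents(ev3)
  expect_identical(eventOffsets(mergeCloseEvents(m)), eventOffsets(m))
})

test_that("endpoints snap to the last strict interior extremum", {
  v <- rep(0, 40)
  v[11:30] <- abs((10:29) - 24)          # unique interior minimum at 24
  rec <- LFPRecording(v, 125, "snap")
  ev <- eventList(10, 30, 125, 40 / 125)
  out <- snapEventEnds(ev, rec)
  expect_identical(eventOffsets(out), 25L)
  expect_identical(eventOnsets(out), 10L)
  # strictly monotone signal inside the event: unchanged
  rec2 <- LFPRecording(seq_len(40), 125, "mono")
  out2 <- snapEventEnds(ev, rec2)
  expect_identical(eventOffsets(out2), 30L)
  # interior max then min: the final (last) extremum wins
  v3 <- rep(0, 40)
  v3[16] <- 5                            # 0-based index 15: maximum
  v3[23] <- -4                           # 0-based index 22: minimum
  out3 <- snapEventEnds(ev, LFPRecording(v3, 125, "mm"))
  expect_identical(eventOffsets(out3), 23L)
})

test_that("the composed correction traces the stated stage order", {
  fs <- 125
  # one 0.05-s blob and one 1-s blob, 0.15 s apart: the short blob is
  # dropped before merging, so the survivor is the long blob alone
  probs <- rep(0, 500)
  probs[101:106] <- 0.9                  # 6 samples = 0.048 s
  probs[126:250] <- 0.9                  # 125 samples = 1 s
  sig <- rnorm(500)
  rec <- LFPRecording(sig, fs, "c")
  out <- correctEvents(probs, rec)
  expect_identical(nEvents(out), 1L)
  expect_identical(eventOnsets(out), 125L)
  expect_lte(eventOffsets(out), 250L)
  expect_identical(nEvents(correctEvents(rep(0, 500), rec)), 0L)
})

test_that("the correction pipeline matches the brute-force reference", {
  set.seed(33)
  fs <- 50
  for (i in 1:300) {
    n <- sample(c(40, 80, 200), 1)
    probs <- runif(n)
    sig <- rnorm(n)
    rec <- LFPRecording(sig, fs, "bf")
    mine <- correctEvents(probs, rec)
    ref <- bruteForceCorrect(probs, sig, fs)
    expect_identical(eventOnsets(mine), as.integer(ref[, "onset"]))
    expect_identical(eventOffsets(mine), as.integer(ref[, "offset"]))
  }
})

test_that("corrected events never overlap and stay within bounds", {
  set.seed(12)
  for (i in 1:30) {
    n <- 400
    probs <- pmin(pmax(stats::filter(runif(n), rep(0.2, 5),
                                     circular = TRUE), 0), 1)
    rec <- LFPRecording(rnorm(n), 125, "b")
    out <- correctEvents(as.numeric(probs), rec)
    if (nEvents(out) > 1) {
      expect_true(all(eventOnsets(out)[-1] >=
                        eventOffsets(out)[-nEvents(out)]))
    }
    expect_true(all(eventOffsets(out) <= n))
    expect_true(all(eventOnsets(out) >= 0))
  }
})

test_that("perfect probabilities on a simulated recording recover the truth", {
  sim <- simulateRecording(fastSimConfig(duration_s = 120, seed = 1,
                                         sle_rate_per_min = 6))
  ds <- downsampleRecording(sim$recording, 125)
  ev125 <- resampleEvents(sim$events, 125)
  lab <- eventsToLabels(ev125, length(samples(ds)))
  out <- correctEvents(as.numeric(labelValues(lab)), ds)
  expect_identical(nEvents(out), nEvents(ev125))
  dOn <- abs(eventOnsets(out) - eventOnsets(ev125)) / 125
  dOff <- abs(eventOffsets(out) - eventOffsets(ev125)) / 125
  expect_true(all(dOn <= 0.1))
  expect_true(all(dOff <= 0.1))
})

test_that("corrected accuracy counts per-sample agreement", {
  truth <- LabelSeries(rep(c(0L, 1L), each = 20), 125)
  evPerfect <- labelsToEvents(truth)
  expect_identical(correctedAccuracy(evPerfect, truth), 1)
  # 39 of 40 agree
  ev39 <- eventList(21, 40, 125, 40 / 125)
  expect_identical(correctedAccuracy(ev39, truth), 0.975)
  # complement labels
  comp <- LabelSeries(rep(c(1L, 0L), each = 20), 125)
  expect_identical(correctedAccuracy(evPerfect, comp), 0)
  expect_error(correctedAccuracy(evPerfect, LabelSeries(0L, 125)),
               "alignment")
  # symmetric under jointly reversing both time axes
  revTruth <- LabelSeries(rev(labelValues(truth)), 125)
  revEv <- labelsToEvents(LabelSeries(rev(labelValues(
    eventsToLabels(ev39, 40))), 125))
  expect_identical(correctedAccuracy(revEv, revTruth),
                   correctedAccuracy(ev39, truth))
})
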