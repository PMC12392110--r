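test_that("isolated distinct troughs inside an event are all detected", {
  fs <- 1000
  v <- rnorm(5000, sd = 0.01)
  troughs <- c(1000, 1500, 2000, 2500)        # 0.5 s apart
  depths <- c(-5, -4, -6, -3)
  v[troughs + 1] <- depths
  ev <- eventList(500, 3000, fs, 5)
  rec <- LFPRecording(v, fs, "sp")
  sp <- detectSpikes(rec, ev)
  expect_true(all(troughs %in% sp$index))
  expect_true(all(sp$event == 1L))
})

test_that("a shallower trough within the window is suppressed", {
  fs <- 1000
  v <- rep(0, 3000)
  v[1001] <- -2                               # 0-based 1000
  v[1101] <- -1                               # 0.1 s later, shallower
  rec <- LFPRecording(v, fs, "sup")
  ev <- eventList(0, 3000, fs, 3)
  sp <- detectSpikes(rec, ev, window_s = 0.165)
  expect_identical(sp$index, 1000L)
  # a constant signal has no spikes
  spC <- detectSpikes(LFPRecording(rep(1, 3000), fs, "c"), ev)
  expect_identical(nrow(spC), 0L)
})

test_that("spike detection matches the brute-force window scan", {
  set.seed(14)
  fs <- 500
  w <- round(0.05 * fs)
  for (i in 1:15) {
    v <- rnorm(1500)
    ev <- eventList(100, 1400, fs, 3)
    rec <- LFPRecording(v, fs, "bf")
    mine <- detectSpikes(rec, ev, window_s = 0.05)$index
    ref <- bruteForceSpikes(v, 100, 1400, w)
    expect_identical(mine, ref)
  }
})

test_that("the four SLE metrics follow their definitions", {
  fs <- 100
  # 600 s of events in a 2,400-s window: fraction 0.25
  ev <- eventList(seq(0, 239) * 1000, seq(0, 239) * 1000 + 250, fs, 2400)
  expect_equal(sleFraction(ev), 0.25)
  expect_equal(sleRate(ev), 6)
  expect_equal(meanSleDuration(ev), 2.5)
  # 288 events in 40 min -> 7.2 per minute
  ev288 <- eventList(seq(0, 287) * 800, seq(0, 287) * 800 + 100, fs, 2400)
  expect_equal(sleRate(ev288), 7.2)
  # 50 spikes over 10 s of total event time -> 5 Hz
  ev10 <- eventList(0, 1000, fs, 60)
  spikes <- data.frame(index = seq_len(50), event = rep(1L, 50))
  expect_equal(spikeFrequency(spikes, ev10), 5)
  # empty events: rate 0, duration and spike frequency missing
  ev0 <- eventList(integer(0), integer(0), fs, 2400)
  expect_equal(sleFraction(ev0), 0)
  expect_equal(sleRate(ev0), 0)
  expect_true(is.na(meanSleDuration(ev0)))
  expect_true(is.na(spikeFrequency(spikes[0, ], ev0)))
  # events tiling the whole window: fraction 1
  evAll <- eventList(0, 240000, fs, 2400)
  expect_equal(sleFraction(evAll), 1)
})

test_that("fraction equals rate times mean duration over 60", {
  set.seed(6)
  for (i in 1:20) {
    fs <- 250
    sim <- simulateRecording(fastSimConfig(duration_s = 120, seed = i))
    ev <- sim$events
    if (nEvents(ev) == 0) next
    expect_equal(sleFraction(ev),
                 sleRate(ev) * meanSleDuration(ev) / 60,
                 tolerance = 1e-12)
  }
})

test_that("pause counting includes leading and trailing gaps", {
  fs <- 10
  ev <- eventList(c(0, 1400), c(100, 1500), fs, 160)
  expect_identical(detectPauses(ev), 1L)        # 130-s interior gap
  ev0 <- eventList(integer(0), integer(0), fs, 2400)
  expect_identical(detectPauses(ev0), 1L)       # one 2,400-s gap
  # events every 60 s: no pause exceeds 120 s
  on <- seq(0, 2340, by = 60) * fs
  evR <- eventList(on, on + 5 * fs, fs, 2400)
  expect_identical(detectPauses(evR), 0L)
  # strict ">": a gap of exactly 120 s is not a pause
  evE <- eventList(c(0, 1210), c(10, 1300), fs, 140)
  expect_identical(detectPauses(evE), 0L)
})

test_that("animal-level aggregation pools events and analyzed time", {
  row <- function(id, animal, frac, dur, rate, sf, analyzed = 1200) {
    data.frame(recording_id = id, group = "naive", hemisphere = "none",
               treatment = "ctrl", animal_id = animal, slice_id = id,
               analyzed_s = analyzed, n_events = rate * analyzed / 60,
               fraction = frac, mean_duration_s = dur,
               rate_per_min = rate, spike_freq_hz = sf, n_pauses = 0L,
               stringsAsFactors = FALSE)
  }
  # one animal, two identical slices: animal metrics equal slice metrics
  tbl <- rbind(row("s1", "a1", 0.3, 2, 9, 10), row("s2", "a1", 0.3, 2, 9, 10))
  agg <- aggregateMetrics(tbl, "animal")
  expect_identical(nrow(agg), 1L)
  expect_equal(agg$fraction, 0.3)
  expect_equal(agg$rate_per_min, 9)
  expect_equal(agg$spike_freq_hz, 10)
  # fractions 0.2 and 0.4 over equal time: animal fraction 0.3
  tbl2 <- rbind(row("s1", "a1", 0.2, 2, 6, 8), row("s2", "a1", 0.4, 2, 12, 8))
  expect_equal(aggregateMetrics(tbl2, "animal")$fraction, 0.3)
  # slice level is the identity
  expect_identical(aggregateMetrics(tbl2, "slice"), tbl2)
  # invariant to slice ordering
  expect_equal(aggregateMetrics(tbl2[2:1, ], "animal")$fraction,
               aggregateMetrics(tbl2, "animal")$fraction)
  # missing animal id is a metadata error
  tbl3 <- tbl2
  tbl3$animal_id <- ""
  expect_error(aggregateMetrics(tbl3, "animal"), "animal_id")
})

test_that("computeSleMetrics assembles one tidy row per recording", {
  sim <- simulateRecording(fastSimConfig(duration_s = 120, seed = 3),
                           recordingId = "m1",
                           meta = list(treatment = "CNB60",
                                       animal_id = "a2",
                                       slice_id = "s4"))
  m <- computeSleMetrics(sim$recording, sim$events)
  expect_identical(nrow(m), 1L)
  expect_identical(m$recording_id, "m1")
  expect_identical(m$treatment, "CNB60")
  expect_equal(m$n_events, nEvents(sim$events))
  expect_equal(m$fraction, sleFraction(sim$events))
  # spikes are detected inside events at a plausible rate; the strict
  # 0.165-s window suppresses shallower neighbors of the ~10-Hz train,
  # so the detected rate sits well below the stamping frequency
  expect_gt(m$spike_freq_hz, 1)
  expect_lt(m$spike_freq_hz, 11)
})
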