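test_that("the periodogram reproduces reference Hann/density values", {
  # reference values computed once with an independent periodogram
  # implementation (Hann window, density scaling, mean removal)
  x <- c(0.5, -1.2, 2.0, 0.3, -0.7, 1.5, -2.1, 0.9,
         0.1, -0.4, 1.1, -1.8, 0.6, 2.2, -0.9, 0.4)
  r <- computePsd(LFPRecording(x, 8, "t"))
  expect_equal(r$frequency, seq(0, 4, by = 0.5))
  expect_equal(r$psd,
               c(0.016049008886244, 0.057405267986689, 0.001882746155964,
                 0.164963809071580, 0.123909115281101, 0.088714302776067,
                 1.558365462018504, 0.792548486513761, 0.057216695129382),
               tolerance = 1e-12)
  # odd length
  r2 <- computePsd(LFPRecording(x[1:15], 8, "t"))
  expect_equal(r2$psd,
               c(0.015600476998172, 0.047550988681184, 0.020531412906389,
                 0.135908345274680, 0.041756869814545, 0.450189082490231,
                 1.580743887829303, 0.399939163279660),
               tolerance = 1e-12)
})

test_that("the periodogram satisfies Parseval and localizes tones", {
  set.seed(21)
  x <- rnorm(20000)
  rec <- LFPRecording(x, 200, "wn")
  ps <- computePsd(rec)
  df <- ps$frequency[2] - ps$frequency[1]
  expect_lt(abs(sum(ps$psd) * df - var(x)) / var(x), 0.05)
  # pure 10-Hz sine: global maximum at the nearest frequency bin
  t <- seq_len(4000) / 200
  tone <- computePsd(LFPRecording(sin(2 * pi * 10 * t), 200, "s"))
  expect_equal(tone$frequency[which.max(tone$psd)], 10, tolerance = 0.06)
  # zero signal: all-zero PSD
  expect_true(all(computePsd(LFPRecording(rep(0, 100), 200, "z"))$psd
                  == 0))
  expect_error(computePsd(LFPRecording(1, 200, "one")), "too short")
})

test_that("band restriction drops DC and normalizes to unit total", {
  set.seed(22)
  rec <- LFPRecording(rnorm(5000) + 10, 200, "n")   # strong DC offset
  ps <- computePsd(rec)
  rn <- restrictAndNormalize(ps)
  expect_true(all(rn$frequency > 0 & rn$frequency <= 30))
  expect_equal(sum(rn$psd), 1, tolerance = 1e-12)
  # power only above the band: normalization error
  fake <- list(frequency = c(35, 40), psd = c(1, 2))
  expect_error(restrictAndNormalize(fake), "normalization error")
})

test_that("binning uses right-closed 0.2-Hz edges over 150 bins", {
  fake <- list(frequency = c(0.2, 0.3, 10.0, 10.05, 30.0),
               psd = c(0.1, 0.2, 0.3, 0.25, 0.15))
  bp <- binPsd(fake, normalized = FALSE)
  expect_identical(length(binCenters(bp)), 150L)
  expect_equal(binCenters(bp)[1], 0.1)
  expect_equal(binCenters(bp)[150], 29.9)
  p <- binPower(bp)
  expect_equal(p[1], 0.1)              # 0.2 Hz falls in bin 1
  expect_equal(p[2], 0.2)              # 0.3 Hz in (0.2, 0.4]
  expect_equal(p[50], 0.3)             # 10.0 Hz in (9.8, 10.0]
  expect_equal(p[51], 0.25)            # 10.05 Hz in (10.0, 10.2]
  expect_equal(p[150], 0.15)           # 30 Hz included
  expect_error(binPsd(fake, bin_width = 0.7), "divide")
})

test_that("normalized binned PSDs sum to one within 1e-9", {
  set.seed(23)
  for (i in 1:5) {
    rec <- LFPRecording(rnorm(4000), 100, "nb")
    bp <- normalizedBinnedPsd(rec)
    expect_lt(abs(sum(binPower(bp)) - 1), 1e-9)
    expect_true(all(binPower(bp) >= 0))
  }
})

test_that("white noise yields an approximately flat binned spectrum", {
  set.seed(24)
  rec <- LFPRecording(rnorm(60 * 200), 200, "flat")
  bp <- normalizedBinnedPsd(rec)
  p <- binPower(bp)
  # ~12 ordinates per bin; the Hann taper correlates neighbors, so the
  # per-bin coefficient of variation sits near 0.4 rather than 1/sqrt(12)
  expect_lt(sd(p) / mean(p), 0.55)
})

test_that("degenerate bootstrap bands collapse onto the input PSD", {
  set.seed(25)
  rec <- LFPRecording(rnorm(4000), 100, "b")
  bp <- normalizedBinnedPsd(rec)
  # all inputs identical: zero-width band equal to that PSD
  band <- bootstrapBand(list(bp, bp, bp), n_resamples = 200, seed = 1)
  bounds <- bandBounds(band)
  expect_equal(bounds$lower, binPower(bp), tolerance = 1e-12)
  expect_equal(bounds$upper, binPower(bp), tolerance = 1e-12)
  # a single recording collapses the same way
  band1 <- bootstrapBand(list(bp), n_resamples = 100, seed = 1)
  expect_equal(bandBounds(band1)$mean, binPower(bp), tolerance = 1e-12)
  expect_error(bootstrapBand(list()), "at least one")
})

test_that("bootstrap bands are deterministic under a fixed seed", {
  set.seed(26)
  psds <- lapply(1:6, function(i)
    normalizedBinnedPsd(LFPRecording(rnorm(2000), 100, "d")))
  b1 <- bandBounds(bootstrapBand(psds, 2000, seed = 7))
  b2 <- bandBounds(bootstrapBand(psds, 2000, seed = 7))
  expect_identical(b1, b2)
  b3 <- bandBounds(bootstrapBand(psds, 2000, seed = 8))
  expect_false(identical(b1$lower, b3$lower))
})

test_that("band width shrinks roughly as one over sqrt(n)", {
  set.seed(27)
  makePsd <- function() normalizedBinnedPsd(
    LFPRecording(rnorm(2000), 100, "w"))
  width <- function(n) {
    b <- bandBounds(bootstrapBand(replicate(n, makePsd(),
                                            simplify = FALSE),
                                  2000, seed = 1))
    mean(b$upper - b$lower)
  }
  w5 <- width(5); w20 <- width(20); w80 <- width(80)
  expect_gt(w5 / w20, 1.4); expect_lt(w5 / w20, 2.9)
  expect_gt(w20 / w80, 1.4); expect_lt(w20 / w80, 2.9)
})

test_that("peak finding reports strict local maxima only", {
  uni <- new("BinnedPSD", binCenters = (1:150 - 0.5) * 0.2,
             power = dnorm((1:150), 70, 15), normalized = FALSE,
             binWidth = 0.2)
  expect_equal(findPsdPeaks(uni), (70 - 0.5) * 0.2)
  flat <- new("BinnedPSD", binCenters = (1:150 - 0.5) * 0.2,
              power = rep(1, 150), normalized = FALSE, binWidth = 0.2)
  expect_identical(length(findPsdPeaks(flat)), 0L)
  two <- new("BinnedPSD", binCenters = (1:10 - 0.5) * 0.2,
             power = c(5, 1, 1, 2, 1, 1, 1, 3, 1, 1),
             normalized = FALSE, binWidth = 0.2)
  expect_equal(findPsdPeaks(two), c(0.1, 0.7, 1.5))
  expect_equal(findPsdPeaks(two, min_frequency = 0.5), c(0.7, 1.5))
})
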