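# Shared fixture builders. Everything is generated in code at test time.

# a labeled, standardized 30-s segment batch from one simulated recording,
# downsampled to the 125-Hz label rate
prepLabeledBatch <- function(seed, duration_s, id,
                             sampling_rate_hz = 2000, ...) {
  cfg <- simRecordingConfig(duration_s = duration_s,
                            sampling_rate_hz = sampling_rate_hz,
                            seed = seed, ...)
  sim <- simulateRecording(cfg, recordingId = id)
  ds <- downsampleRecording(sim$recording, 125)
  ev <- resampleEvents(sim$events, 125)
  lab <- eventsToLabels(ev, length(samples(ds)))
  standardizeBatch(segmentRecording(ds, lab, 30))
}

# cheap simulator settings: identical event process, lower sampling rate
fastSimConfig <- function(duration_s = 300, seed = 1, ...) {
  simRecordingConfig(duration_s = duration_s, sampling_rate_hz = 250,
                     seed = seed, ...)
}

tinyDetectorConfig <- function(channels = 4, n_blocks = 4) {
  detectorConfig(n_blocks = n_blocks, channels = channels,
                 dilations = 2^(0:(n_blocks - 1)))
}

# independent brute-force reference for the post-processing rules,
# working directly on label vectors with plain loops
bruteForceCorrect <- function(probs, signal, rate, threshold = 0.5,
                              min_dur = 0.1, merge_gap = 0.2) {
  lab <- as.integer(probs >= threshold)
  n <- length(lab)
  # maximal runs of ones by linear scan
  ev <- list(); inEv <- FALSE
  for (i in seq_len(n)) {
    if (lab[i] == 1L && !inEv) { start <- i; inEv <- TRUE }
    if (inEv && (lab[i] == 0L || i == n)) {
      end <- if (lab[i] == 0L) i - 1L else i
      ev[[length(ev) + 1L]] <- c(start, end)
      inEv <- FALSE
    }
  }
  # drop shorter than min_dur (strict)
  ev <- Filter(function(e) (e[2] - e[1] + 1) / rate >= min_dur - 1e-12, ev)
  # transitively merge gaps < merge_gap (strict)
  if (length(ev) > 1) {
    merged <- list(ev[[1]])
    for (i in 2:length(ev)) {
      last <- merged[[length(merged)]]
      gap <- (ev[[i]][1] - last[2] - 1) / rate
      if (gap < merge_gap - 1e-12) {
        merged[[length(merged)]] <- c(last[1], ev[[i]][2])
      } else {
        merged[[length(merged) + 1L]] <- ev[[i]]
      }
    }
    ev <- merged
  }
  # snap each end to the last strict interior extremum
  ev <- lapply(ev, function(e) {
    lastEx <- NA
    if (e[2] - e[1] >= 2) {
      for (k in (e[1] + 1):(e[2] - 1)) {
        if ((signal[k] > signal[k - 1] && signal[k] > signal[k + 1]) ||
            (signal[k] < signal[k - 1] && signal[k] < signal[k + 1])) {
          lastEx <- k
        }
      }
    }
    if (!is.na(lastEx)) c(e[1], lastEx) else e
  })
  if (length(ev) == 0) {
    return(cbind(onset = integer(0), offset = integer(0)))
  }
  m <- do.call(rbind, ev)
  cbind(onset = m[, 1] - 1L, offset = m[, 2])   # 0-based half-open
}

# brute-force O(n*w) spike scan: strict window minimum, interior samples
bruteForceSpikes <- function(v, onset0, offset0, w) {
  n <- length(v)
  out <- integer(0)
  for (p in 2:(n - 1)) {
    if (p - 1 < onset0 || p - 1 >= offset0) next   # 0-based inside
    lo <- max(1L, p - w); hi <- min(n, p + w)
    others <- v[setdiff(lo:hi, p)]
    if (all(v[p] < others)) out <- c(out, p - 1L)
  }
  out
}

# two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins
fisherEnumeration <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    stats::dhyper(k, c1, n - c1, r1)
  }, numeric(1))
  pObs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# exact Kruskal-Wallis permutation p by enumerating all assignments of
# the pooled values to the group sizes (independent of the package's
# enumeration: uses stats::kruskal.test for the statistic)
kwPermutationOracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, integer(1))
  n <- length(x)
  stat <- function(assign) {
    g <- factor(assign, levels = seq_along(sizes))
    unname(stats::kruskal.test(x, g)$statistic)
  }
  obs <- stat(rep(seq_along(sizes), sizes))
  perms <- allAssignments(n, sizes)
  stats <- apply(perms, 1, stat)
  mean(stats >= obs - 1e-12)
}

# all distinct ways to assign n items to groups of the given sizes
allAssignments <- function(n, sizes) {
  rec <- function(remaining, sizes) {
    if (length(sizes) == 1) {
      return(matrix(remaining, nrow = 1))
    }
    out <- list()
    picks <- utils::combn(remaining, sizes[1], simplify = FALSE)
    for (p in picks) {
      rest <- rec(setdiff(remaining, p), sizes[-1])
      out[[length(out) + 1L]] <- cbind(matrix(rep(p, nrow(rest)),
                                              nrow = nrow(rest),
                                              byrow = TRUE), rest)
    }
    do.call(rbind, out)
  }
  idxPerms <- rec(seq_len(n), sizes)
  # convert item-order rows to assignment vectors
  t(apply(idxPerms, 1, function(row) {
    assign <- integer(n)
    pos <- 1L
    for (gi in seq_along(sizes)) {
      assign[row[pos:(pos + sizes[gi] - 1L)]] <- gi
      pos <- pos + sizes[gi]
    }
    assign
  }))
}

# independent Dunn + Holm reference, straight from the formulas
dunnHolmOracle <- function(groups, pairs) {
  x <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, integer(1))
  g <- rep(names(groups), sizes)
  N <- length(x)
  r <- rank(x)
  mr <- vapply(names(groups), function(k) mean(r[g == k]), numeric(1))
  ties <- table(x)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  praw <- vapply(pairs, function(pr) {
    z <- (mr[[pr[1]]] - mr[[pr[2]]]) /
      sqrt(s2 * (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  # Holm step-down by hand
  m <- length(praw)
  o <- order(praw)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * praw[o[i]])
    adj[o[i]] <- min(1, running)
  }
  list(p_raw = unname(praw), p_adj = adj)
}

# deterministic band-limited test signal: a few tones below 40 Hz
fastSimBandlimited <- function(n, fs = 2000) {
  t <- (seq_len(n) - 1) / fs
  sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 7 * t + 1) +
    0.3 * sin(2 * pi * 19 * t + 2) + 0.2 * sin(2 * pi * 31 * t + 3)
}

# row-bind several segment batches
bindTestBatches <- function(batches) sleseg:::bindBatches(batches)
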