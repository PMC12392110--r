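# Internal numeric helpers shared across modules.

# Zero-phase low-pass via FFT with a raised-cosine rolloff.
# Gain is 1 for f <= cutoff, falls smoothly to 0 at cutoff + rolloff.
# Zero phase by construction (real gain applied to the spectrum).
fftLowpass <- function(x, fs, cutoff, rolloff = 3) {
  n <- length(x)
  if (n < 2L || cutoff >= fs / 2) return(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n      # folded frequency axis
  gain <- rep(1, n)
  ramp <- f > cutoff & f < cutoff + rolloff
  gain[f >= cutoff + rolloff] <- 0
  gain[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - cutoff) / rolloff))
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# Deterministic seed splitting: one base seed plus a counter yields
# independent-looking 31-bit seeds regardless of generation order.
splitSeed <- function(seed, counter) {
  a <- (as.numeric(seed) %% 2147483647) + 1
  x <- (a * 48271) %% 2147483647
  x <- (x + as.numeric(counter) * 69621) %% 2147483647
  x <- (x * 16807) %% 2147483647
  as.integer(x)
}

assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# run-length extraction of maximal 1-runs; returns 0-based half-open indices
runsOfOnes <- function(labels) {
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  cbind(onset = starts[keep], offset = ends[keep])
}
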