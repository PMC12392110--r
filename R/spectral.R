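#' Periodogram power spectral density of a recording
#'
#' One-sided periodogram with a (periodic) Hann taper and density
#' scaling: the mean is removed, the tapered signal is Fourier
#' transformed, and `|X(f)|^2` is scaled by `2 / (fs * sum(w^2))`
#' (factor 1 at DC and Nyquist), so that `sum(psd) * fs / n`
#' approximates the signal variance (Parseval).
#'
#' @param recording an [LFPRecording-class] (length >= 2). Pass the
#'   final 40 min of a session via [selectAnalysisWindow()] first when
#'   reproducing the whole-recording analysis.
#' @param final_s if non-`NULL`, restrict to the final `final_s` seconds
#'   before computing.
#' @return a list with `frequency` (Hz, from 0 to Nyquist) and `psd`
#'   (density units, signal^2/Hz).
#' @export
computePsd <- function(recording, final_s = NULL) {
  stopifnot(is(recording, "LFPRecording"))
  x <- recording@samples
  fs <- recording@samplingRate
  if (!is.null(final_s)) {
    n0 <- round(final_s * fs)
    if (n0 > length(x)) {
      stop("recording shorter than the requested final window",
           call. = FALSE)
    }
    x <- x[(length(x) - n0 + 1):length(x)]
  }
  n <- length(x)
  if (n < 2) stop("recording too short for a periodogram", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)   # periodic Hann
  x <- (x - mean(x)) * w
  X <- stats::fft(x)
  nf <- n %/% 2 + 1
  p <- (Mod(X[seq_len(nf)])^2) / (fs * sum(w^2))
  if (n %% 2 == 0) {
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  } else {
    p[2:nf] <- 2 * p[2:nf]
  }
  list(frequency = (seq_len(nf) - 1) * fs / n, psd = p)
}

#' Restrict a periodogram to (0, 30] Hz and normalize to unit total
#'
#' Frequency components at or below 0 Hz and above `fmax` are removed;
#' the remaining values are divided by their total, so they sum to 1.
#'
#' @param psd a list with `frequency` and `psd` (from [computePsd()]).
#' @param fmax upper band edge in Hz (default 30, inclusive).
#' @return a list with the restricted `frequency` and normalized `psd`.
#' @export
restrictAndNormalize <- function(psd, fmax = 30) {
  keep <- psd$frequency > 0 & psd$frequency <= fmax
  vals <- psd$psd[keep]
  tot <- sum(vals)
  if (tot <= 0) {
    stop("normalization error: no power within (0, ", fmax, "] Hz",
         call. = FALSE)
  }
  list(frequency = psd$frequency[keep], psd = vals / tot)
}

#' Bin an in-band PSD into fixed-width frequency bins
#'
#' Bins have right-closed edges `(0, 0.2], (0.2, 0.4], ..., (29.8, 30]`
#' (so a component at exactly 0.2 Hz falls into the first bin and 30 Hz
#' is included); a bin's value is the sum of its member PSD ordinates,
#' so a normalized input yields bins that still sum to 1.
#'
#' @param psd a list with `frequency` and `psd` covering `(0, fmax]`.
#' @param bin_width bin width in Hz (default 0.2); must divide `fmax`.
#' @param fmax band edge in Hz (default 30).
#' @param normalized whether the input was normalized to unit total.
#' @return a [BinnedPSD-class] with `fmax / bin_width` bins.
#' @export
binPsd <- function(psd, bin_width = 0.2, fmax = 30, normalized = TRUE) {
  nb <- fmax / bin_width
  if (abs(nb - round(nb)) > 1e-9) {
    stop("bin_width must divide the frequency band", call. = FALSE)
  }
  nb <- as.integer(round(nb))
  idx <- as.integer(ceiling(psd$frequency / bin_width - 1e-9))
  idx[idx < 1L] <- 1L
  ok <- idx <= nb
  power <- numeric(nb)
  agg <- tapply(psd$psd[ok], idx[ok], sum)
  power[as.integer(names(agg))] <- as.numeric(agg)
  new("BinnedPSD", binCenters = (seq_len(nb) - 0.5) * bin_width,
      power = power, normalized = isTRUE(normalized),
      binWidth = bin_width)
}

#' Normalized, binned PSD of a recording in one call
#'
#' Convenience composition: [computePsd()], [restrictAndNormalize()],
#' [binPsd()].
#'
#' @inheritParams computePsd
#' @inheritParams binPsd
#' @return a [BinnedPSD-class].
#' @export
normalizedBinnedPsd <- function(recording, final_s = NULL,
                                bin_width = 0.2, fmax = 30) {
  binPsd(restrictAndNormalize(computePsd(recording, final_s), fmax),
         bin_width, fmax, normalized = TRUE)
}

#' Bootstrap confidence band across recordings' binned PSDs
#'
#' Resamples recordings with replacement (each recording is one sample),
#' recomputes the across-recording mean per bin, and takes percentile
#' intervals of the resulting bootstrap distribution.
#'
#' @param psds list of [BinnedPSD-class] objects on identical bins.
#' @param n_resamples number of bootstrap resamples (default 1e4).
#' @param level confidence level (default 0.95).
#' @param seed seed for the resampling.
#' @return a [BootstrapBand-class].
#' @export
bootstrapBand <- function(psds, n_resamples = 1e4, level = 0.95,
                          seed = 1L) {
  if (length(psds) < 1) {
    stop("at least one recording PSD is required", call. = FALSE)
  }
  mats <- lapply(psds, binPower)
  nb <- length(mats[[1]])
  if (any(vapply(mats, length, integer(1)) != nb)) {
    stop("all PSDs must share the same bins", call. = FALSE)
  }
  P <- do.call(rbind, mats)                       # n x bins
  n <- nrow(P)
  set.seed(seed)
  counts <- stats::rmultinom(n_resamples, n, rep(1 / n, n)) / n   # n x R
  boot <- crossprod(counts, P)                    # R x bins
  alpha <- (1 - level) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  new("BootstrapBand", binCenters = psds[[1]]@binCenters,
      mean = colMeans(P), lower = pmin(qs[1, ], colMeans(P)),
      upper = pmax(qs[2, ], colMeans(P)), level = level,
      nResamples = as.integer(n_resamples))
}

#' Local peaks of a binned PSD
#'
#' Strict local maxima over bins (each strictly greater than its
#' immediate neighbors; the first and last bin qualify by a one-sided
#' comparison, since the band is artificially truncated there),
#' optionally restricted to frequencies above `min_frequency`. A flat
#' PSD has no strict peaks.
#'
#' @param bpsd a [BinnedPSD-class].
#' @param min_frequency return only peaks with bin center strictly
#'   above this frequency (default 0).
#' @return numeric vector of peak bin-center frequencies, ordered by
#'   frequency.
#' @export
findPsdPeaks <- function(bpsd, min_frequency = 0) {
  stopifnot(is(bpsd, "BinnedPSD"))
  p <- bpsd@power
  nb <- length(p)
  if (nb == 0) return(numeric(0))
  isPeak <- logical(nb)
  if (nb == 1) {
    isPeak[1] <- TRUE
  } else {
    isPeak[1] <- p[1] > p[2]
    isPeak[nb] <- p[nb] > p[nb - 1]
    if (nb > 2) {
      i <- 2:(nb - 1)
      isPeak[i] <- p[i] > p[i - 1] & p[i] > p[i + 1]
    }
  }
  centers <- bpsd@binCenters[isPeak]
  sort(centers[centers > min_frequency])
}
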