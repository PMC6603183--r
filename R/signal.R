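#' Zero-phase band-pass filter
#'
#' Filters an LFP trace with a Butterworth band-pass applied forward and
#' backward ([signal::filtfilt()]), so the output is zero-phase: event
#' timing is preserved, which matters downstream when spikes are aligned to
#' event centers. The filter is designed with -3 dB points at `low` and
#' `high`; the two-pass application doubles the attenuation (band edges end
#' up at -6 dB), leaving the passband interior at unit gain.
#'
#' @param record an [lfp_record()], or a numeric vector (then `fs` is
#'   required).
#' @param low,high band edges in Hz; defaults 20 and 40.
#' @param fs sampling rate in Hz when `record` is a bare vector.
#' @param order Butterworth prototype order (the band-pass has twice this
#'   order per pass).
#' @return numeric vector of filtered samples, same length as the input.
#' @examples
#' rec <- lfp_record(rnorm(4000), fs = 2000)
#' f <- bandpass_filter(rec, 20, 40)
#' @export
bandpass_filter <- function(record, low = 20, high = 40, fs = NULL,
                            order = 3) {
  if (inherits(record, "lfp_record")) {
    x <- record$samples
    fs <- record$fs
  } else {
    check_arg(!is.null(fs), "'fs' is required when 'record' is a vector")
    x <- as.numeric(record)
  }
  check_arg(is.numeric(low) && is.numeric(high) && length(low) == 1L &&
              length(high) == 1L, "'low' and 'high' must be scalars")
  check_arg(low > 0 && high > low && high < fs / 2,
            sprintf("band (%g, %g) Hz must satisfy 0 < low < high < fs/2 = %g",
                    low, high, fs / 2))
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Sliding-window z-scored RMS envelope
#'
#' Computes the root-mean-square amplitude of a (typically band-pass
#' filtered) signal over a sliding window, then z-scores the RMS series
#' using its mean and SD over the entire analyzed period. The z-scored
#' envelope is the quantity thresholded by [detect_events()]; z-scoring
#' makes detection insensitive to absolute amplitude and to broadband noise
#' color. The default 100-ms window matches the conventional bin size for
#' 20-40 Hz event extraction; the default 10-ms step gives overlapping
#' windows so event durations can be resolved finer than the window itself
#' (set `step = window` for non-overlapping bins). Windows that would
#' extend past either edge of the record are dropped, not padded.
#'
#' @param x numeric vector of filtered samples.
#' @param fs sampling rate in Hz.
#' @param window window length in seconds (default 0.1).
#' @param step hop between window starts in seconds (default 0.01).
#' @return an object of class `envelope_series`: list with `values`
#'   (z-scored RMS), `times` (window centers, seconds), `window`, `step`,
#'   `fs`, and `raw` (the un-normalized RMS values).
#' @examples
#' env <- zscored_rms(rnorm(20000), fs = 2000)
#' c(mean(env$values), sd(env$values))
#' @export
zscored_rms <- function(x, fs, window = 0.1, step = 0.01) {
  x <- as.numeric(x)
  check_arg(window > 0 && step > 0, "'window' and 'step' must be positive")
  w <- max(1L, round(window * fs))
  s <- max(1L, round(step * fs))
  n <- length(x)
  check_arg(n >= w, "signal shorter than one RMS window")
  starts <- seq.int(1L, n - w + 1L, by = s)
  csum <- c(0, cumsum(x^2))
  rms <- sqrt((csum[starts + w] - csum[starts]) / w)
  mu <- mean(rms)
  sdev <- stats::sd(rms)
  if (!is.finite(sdev) || sdev <= 1e-9 * mu) {
    # covers constant signals and analytically constant envelopes (e.g. a
    # pure tone whose period divides the window), where z-scoring would
    # only amplify rounding noise
    degenerate_error("RMS envelope is (numerically) constant; cannot z-score")
  }
  times <- (starts - 1 + (w - 1) / 2) / fs  # window centers
  structure(
    list(values = (rms - mu) / sdev, times = times,
         window = w / fs, step = s / fs, fs = fs, raw = rms),
    class = "envelope_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("<envelope_series> %d windows (%.0f ms window, %.0f ms step) over %.1f s\n",
              length(x$values), 1000 * x$window, 1000 * x$step,
              utils::tail(x$times, 1) - x$times[1] + x$window))
  invisible(x)
}

#' Morlet wavelet spectrogram
#'
#' Time-frequency power via convolution with complex Morlet wavelets,
#' implemented in the frequency domain: each frequency row is the squared
#' magnitude of the analytic signal obtained by multiplying the FFT of the
#' trace with a Gaussian window centered on that frequency (width set by
#' `n_cycles`). Power is returned at the native sampling resolution, i.e.
#' 0.5-ms time bins at a 2-kHz sampling rate. With `zscore = TRUE` each
#' frequency row is z-scored across the entire analyzed period, the usual
#' normalization for comparing transient events against ongoing background
#' power.
#'
#' Frequencies span `fmin`..`fmax` on a logarithmic grid by default (set
#' `log_freqs = FALSE` for linear). Memory grows as
#' `n_freqs * length(record)`; for long records compute spectrograms on
#' excerpts around events of interest.
#'
#' @param record an [lfp_record()] or numeric vector (then `fs` required).
#' @param fmin,fmax frequency range in Hz; defaults 1 and 250.
#' @param n_freqs number of frequency bins.
#' @param n_cycles Morlet width in cycles (default 7).
#' @param zscore z-score each frequency row over the whole record?
#' @param log_freqs logarithmic frequency grid?
#' @param fs sampling rate when `record` is a bare vector.
#' @return an object of class `spectrogram`: list with `power`
#'   (`n_freqs` x `n_samples` matrix), `freqs` (Hz) and `times` (s).
#' @export
morlet_spectrogram <- function(record, fmin = 1, fmax = 250, n_freqs = 50,
                               n_cycles = 7, zscore = FALSE,
                               log_freqs = TRUE, fs = NULL) {
  if (inherits(record, "lfp_record")) {
    x <- record$samples
    fs <- record$fs
  } else {
    check_arg(!is.null(fs), "'fs' is required when 'record' is a vector")
    x <- as.numeric(record)
  }
  check_arg(fmin > 0 && fmax > fmin, "'fmin' and 'fmax' must satisfy 0 < fmin < fmax")
  check_arg(fmax <= fs / 2,
            sprintf("'fmax' = %g Hz exceeds the Nyquist frequency %g Hz", fmax, fs / 2))
  n <- length(x)
  freqs <- if (log_freqs) exp(seq(log(fmin), log(fmax), length.out = n_freqs))
           else seq(fmin, fmax, length.out = n_freqs)
  X <- stats::fft(x)
  fgrid <- (seq_len(n) - 1) / n * fs      # FFT bin frequencies, 0..fs
  pos <- fgrid <= fs / 2                   # analytic signal: keep positive half
  power <- matrix(0, nrow = n_freqs, ncol = n,
                  dimnames = list(signif(freqs, 6), NULL))
  for (k in seq_len(n_freqs)) {
    f <- freqs[k]
    sigma_t <- n_cycles / (2 * pi * f)
    H <- numeric(n)
    H[pos] <- 2 * exp(-0.5 * ((fgrid[pos] - f) * 2 * pi * sigma_t)^2)
    w <- stats::fft(X * H, inverse = TRUE) / n
    power[k, ] <- Mod(w)^2
  }
  if (zscore) {
    mu <- rowMeans(power)
    sdev <- apply(power, 1L, stats::sd)
    check_arg(all(sdev > 0),
              "cannot z-score a spectrogram with constant-power frequency rows")
    power <- (power - mu) / sdev
  }
  structure(
    list(power = power, freqs = freqs, times = (seq_len(n) - 1) / fs,
         n_cycles = n_cycles, zscored = zscore),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freqs (%.3g-%.3g Hz) x %d time bins%s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$power),
              if (x$zscored) ", z-scored per frequency" else ""))
  invisible(x)
}

#' @export
plot.spectrogram <- function(x, ...) {
  graphics::image(x$times, x$freqs, t(x$power), xlab = "Time (s)",
                  ylab = "Frequency (Hz)", log = "y",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
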