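# Signal primitives: band-pass response, z-scored RMS envelope, Morlet
# spectrogram.

test_that("band-pass passes the band and rejects out-of-band tones", {
  fs <- 2000
  t <- (0:(10 * fs - 1)) / fs
  mid <- 5000:15000  # interior, clear of filter edge transients

  f30 <- bandpass_filter(sin(2 * pi * 30 * t), 20, 40, fs = fs)
  expect_equal(max(abs(f30[mid])), 1, tolerance = 0.05)

  x100 <- sin(2 * pi * 100 * t)
  f100 <- bandpass_filter(x100, 20, 40, fs = fs)
  expect_lt(sd(f100) / sd(x100), 0.01)

  expect_identical(bandpass_filter(numeric(4000) , 20, 40, fs = fs),
                   numeric(4000))
})

test_that("band-pass rejects bands outside (0, Nyquist)", {
  x <- rnorm(4000)
  expect_error(bandpass_filter(x, 0, 40, fs = 2000),
               class = "lfpevents_argument_error")
  expect_error(bandpass_filter(x, 20, 1200, fs = 2000),
               class = "lfpevents_argument_error")
  expect_error(bandpass_filter(x, 40, 20, fs = 2000),
               class = "lfpevents_argument_error")
})

test_that("band-pass is near-idempotent on band-limited input", {
  # input already inside the passband: a second application changes little
  fs <- 2000
  t <- (0:(20 * fs - 1)) / fs
  set.seed(1)
  x <- sin(2 * pi * 28 * t) + 0.5 * sin(2 * pi * 33 * t + 1)
  once <- bandpass_filter(x, 20, 40, fs = fs)
  twice <- bandpass_filter(once, 20, 40, fs = fs)
  mid <- (5 * fs):(15 * fs)
  rel_change <- sqrt(mean((twice[mid] - once[mid])^2)) /
    sqrt(mean(once[mid]^2))
  expect_lt(rel_change, 0.05)
})

test_that("zscored_rms matches a brute-force oracle on a toy vector", {
  x <- c(1, -2, 3, 0, 4, 1, -1, 2, 0, -3, 2, 2, -4, 1, 0, 5, -2, 1, 3, -1)
  # fs = 1 Hz, 4-sample non-overlapping bins -> oracle by direct loop
  starts <- c(1, 5, 9, 13, 17)
  rms <- vapply(starts, function(s) sqrt(mean(x[s:(s + 3)]^2)), numeric(1))
  oracle <- (rms - mean(rms)) / sd(rms)
  env <- zscored_rms(x, fs = 1, window = 4, step = 4)
  expect_equal(env$values, oracle, tolerance = 1e-12)
  expect_equal(env$times, starts - 1 + 1.5)  # window centers
})

test_that("zscored_rms output is normalized to mean 0 and SD 1", {
  fs <- 2000
  set.seed(7)
  inputs <- list(rnorm(5 * fs),
                 sin(2 * pi * 30 * (0:(5 * fs - 1)) / fs) +
                   0.2 * rnorm(5 * fs),
                 cumsum(rnorm(5 * fs)))
  for (x in inputs) {
    env <- zscored_rms(x, fs)
    expect_lt(abs(mean(env$values)), 1e-9)
    expect_lt(abs(sd(env$values) - 1), 1e-9)
  }
})

test_that("zscored_rms raises on degenerate input rather than yielding NaN", {
  expect_error(zscored_rms(rep(2, 4000), fs = 2000),
               class = "lfpevents_degenerate_error")
  expect_error(zscored_rms(rnorm(100), fs = 2000),
               class = "lfpevents_argument_error")  # shorter than one window
})

test_that("Morlet spectrogram localizes tones at the right frequencies", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  sp <- morlet_spectrogram(sin(2 * pi * 30 * t), fmin = 5, fmax = 100,
                           n_freqs = 40, fs = fs)
  peak_row <- unname(which.max(rowMeans(sp$power)))
  expect_equal(peak_row, which.min(abs(sp$freqs - 30)))

  # two tones -> two local maxima at the nearest bins
  x2 <- sin(2 * pi * 10 * t) + sin(2 * pi * 100 * t)
  sp2 <- morlet_spectrogram(x2, fmin = 5, fmax = 200, n_freqs = 60, fs = fs)
  mp <- rowMeans(sp2$power)
  local_max <- which(diff(sign(diff(mp))) == -2) + 1L
  expect_true(which.min(abs(sp2$freqs - 10)) %in% local_max)
  expect_true(which.min(abs(sp2$freqs - 100)) %in% local_max)
})

test_that("Morlet spectrogram basics: zeros, scaling, z-scoring, errors", {
  fs <- 1000
  zero <- morlet_spectrogram(numeric(fs), fmin = 5, fmax = 100,
                             n_freqs = 10, fs = fs)
  expect_true(all(zero$power == 0))

  set.seed(2)
  x <- rnorm(fs)
  p1 <- morlet_spectrogram(x, fmin = 5, fmax = 100, n_freqs = 10, fs = fs)
  p3 <- morlet_spectrogram(3 * x, fmin = 5, fmax = 100, n_freqs = 10, fs = fs)
  expect_equal(p3$power, 9 * p1$power, tolerance = 1e-10)

  pz <- morlet_spectrogram(x, fmin = 5, fmax = 100, n_freqs = 10, fs = fs,
                           zscore = TRUE)
  expect_true(all(abs(rowMeans(pz$power)) < 1e-9))

  expect_error(morlet_spectrogram(x, fmin = 5, fmax = 600, fs = fs),
               class = "lfpevents_argument_error")
})
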