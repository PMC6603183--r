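# Envelope-threshold event detection and its descriptive statistics.

test_that("injected bursts are recovered one for one", {
  sim <- burst_record(duration = 1000, n_events = 5, amplitude = 10,
                      burst_dur = 0.4, seed = 101)
  ev <- detect_events(sim$record, estimate_freq = FALSE)
  expect_equal(nrow(ev), 5L)
  ov <- overlap_counts(ev, sim$ground_truth)
  expect_true(all(ov$truth_hit))
  expect_true(all(ov$det_hit))
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$offset[-nrow(ev)] <= ev$onset[-1]))  # non-overlapping
  expect_equal(ev$center, (ev$onset + ev$offset) / 2)
  expect_true(all(ev$peak_z >= 4))
})

test_that("the strict >200 ms duration criterion rejects short bursts", {
  for (seed in 1:5) {
    short <- burst_record(duration = 120, n_events = 4, burst_dur = 0.15,
                          amplitude = 10, seed = seed)
    expect_equal(nrow(detect_events(short$record, estimate_freq = FALSE)), 0L)
    long <- burst_record(duration = 120, n_events = 4, burst_dur = 0.5,
                         amplitude = 10, seed = seed)
    expect_equal(nrow(detect_events(long$record, estimate_freq = FALSE)), 4L)
  }
})

test_that("pure noise at threshold 6 yields no events", {
  for (seed in 1:5) {
    noise <- generate_lfp(100, fs = 2000, spec = event_spec(rate = 0),
                          seed = seed)
    ev <- detect_events(noise$record,
                        detection_params(threshold_z = 6),
                        estimate_freq = FALSE)
    expect_equal(nrow(ev), 0L)
  }
})

test_that("off-band 60 Hz bursts produce no 20-40 Hz detections", {
  for (seed in 1:5) {
    sim <- burst_record(duration = 120, n_events = 4, freq = 60,
                        amplitude = 10, seed = seed)
    expect_equal(nrow(detect_events(sim$record, estimate_freq = FALSE)), 0L)
  }
})

test_that("detected durations track ground truth in the sparse regime", {
  sim <- burst_record(duration = 600, n_events = 8, burst_dur = 0.5,
                      amplitude = 8, seed = 77)
  ev <- detect_events(sim$record, estimate_freq = FALSE)
  expect_equal(nrow(ev), 8L)
  p <- attr(ev, "params")
  tol <- p$rms_step + p$rms_window / 2
  expect_true(all(abs(ev$duration - sim$ground_truth$duration) <= tol + 1e-6))
})

test_that("event_rate is count over analyzed duration", {
  ev7 <- structure(data.frame(onset = 1:7), class = c("oscillatory_events",
                                                      "data.frame"))
  expect_equal(event_rate(ev7, 350), 0.02)
  expect_equal(event_rate(ev7[0, , drop = FALSE], 600), 0)
  expect_error(event_rate(ev7, 0), class = "lfpevents_argument_error")
})

test_that("inter-event intervals and cutoff fractions follow the strict-< rule", {
  ev <- data.frame(onset = c(0, 5, 12, 40))
  res <- inter_event_intervals(ev)
  expect_equal(res$intervals, c(5, 7, 28))
  expect_equal(unname(res$fraction_within["10"]), 2 / 3)
  expect_equal(unname(res$fraction_within["20"]), 2 / 3)

  single <- inter_event_intervals(data.frame(onset = 3))
  expect_length(single$intervals, 0L)
  expect_true(all(is.na(single$fraction_within)))
  expect_false(attr(single$fraction_within, "defined"))

  spaced <- inter_event_intervals(data.frame(onset = seq(0, 40, by = 10)))
  expect_equal(unname(spaced$fraction_within["10"]), 0)  # boundary is strict
})

test_that("oscillation frequency estimates recover injected frequencies", {
  sim <- burst_record(duration = 300, n_events = 6, freq = 32,
                      amplitude = 10, seed = 8)
  ev <- detect_events(sim$record)
  expect_true(all(abs(ev$osc_freq - 32) <= 2))

  # band-edge bursts straddle the detection band correctly
  lo <- burst_record(duration = 200, n_events = 3, freq = 20,
                     amplitude = 10, seed = 9)
  hi <- burst_record(duration = 200, n_events = 3, freq = 40,
                     amplitude = 10, seed = 10)
  f_lo <- detect_events(lo$record)$osc_freq
  f_hi <- detect_events(hi$record)$osc_freq
  expect_true(all(f_lo < 25))
  expect_true(all(f_hi > 35))

  expect_error(estimate_osc_frequency(sim$record,
                                      list(onset = 500, offset = 501)),
               class = "lfpevents_argument_error")
})

test_that("threshold sweep rates are non-increasing and saturate for strong bursts", {
  sim <- burst_record(duration = 200, n_events = 5, amplitude = 10, seed = 31)
  sw <- threshold_sweep(sim$record)
  expect_equal(sw$threshold, seq(3, 6, by = 0.5))
  expect_true(all(diff(sw$rate) <= 0))
  # far-above-threshold bursts are counted identically at every threshold
  expect_equal(length(unique(sw$n_events)), 1L)
  expect_equal(sw$n_events[1], 5)

  noise <- generate_lfp(100, fs = 2000, spec = event_spec(rate = 0), seed = 32)
  swn <- threshold_sweep(noise$record)
  expect_true(all(diff(swn$rate) <= 0))

  expect_error(threshold_sweep(sim$record, thresholds = c(5, 3)),
               class = "lfpevents_argument_error")
})

test_that("event counts are monotone in the minimum-duration criterion", {
  sim <- generate_lfp(300, fs = 2000,
                      spec = event_spec(rate = 0.1, amplitude = 8,
                                        duration_mean = 0.3,
                                        duration_sd = 0.15),
                      seed = 55)
  durs <- c(0.1, 0.2, 0.3, 0.5)
  counts <- vapply(durs, function(md) {
    nrow(detect_events(sim$record, detection_params(min_duration = md),
                       estimate_freq = FALSE))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("region-wise rate comparisons are Bonferroni-adjusted pairwise tests", {
  same <- list(vmPFC = c(0.04, 0.05, 0.06), dmPFC = c(0.04, 0.05, 0.06))
  res_same <- compare_region_rates(same)
  expect_equal(res_same$p_adj, 1)

  rates <- list(vmPFC = rep(0.05, 10), dmPFC = rep(0, 10), ACC = rep(0, 10))
  res <- compare_region_rates(rates)
  expect_equal(nrow(res), 3L)
  vs <- res[res$region_a == "vmPFC", ]
  expect_true(all(vs$p_adj < 0.05))

  # planned-contrast mode: only the two comparisons against vmPFC, m = 2
  planned <- compare_region_rates(rates,
                                  pairs = rbind(c("vmPFC", "dmPFC"),
                                                c("vmPFC", "ACC")), m = 2)
  expect_equal(nrow(planned), 2L)
  expect_equal(planned$p_adj, pmin(1, 2 * planned$p))

  expect_error(compare_region_rates(list(vmPFC = 1:3)),
               class = "lfpevents_argument_error")
})

test_that("sub-threshold gap merging is off by default and works when enabled", {
  # two strong bursts 0.15 s apart: separate events by default, one merged
  # event when the gap parameter covers the separation
  fs <- 2000
  t <- (0:(60 * fs - 1)) / fs
  set.seed(3)
  x <- rnorm(length(t))
  for (on in c(20, 20.45)) {
    idx <- which(t >= on & t <= on + 0.3)
    x[idx] <- x[idx] + 10 * sin(2 * pi * 30 * t[idx])
  }
  rec <- lfp_record(x, fs)
  plain <- detect_events(rec, estimate_freq = FALSE)
  merged <- detect_events(rec, detection_params(merge_gap = 0.3),
                          estimate_freq = FALSE)
  expect_equal(nrow(plain), 2L)
  expect_equal(nrow(merged), 1L)
  expect_gt(merged$duration[1], 0.6)
})
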