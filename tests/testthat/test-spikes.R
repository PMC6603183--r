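# Spike-train analyses: rates, rasters, PETHs, modulation, group tests.

test_that("session firing rate and the interneuron flag behave as specified", {
  tr <- spike_train(seq(0.5, 299.5, by = 1))  # 300 spikes over 300 s
  expect_equal(session_firing_rate(tr, c(0, 300)), 1)
  expect_equal(session_firing_rate(spike_train(numeric(0)), c(0, 10)), 0)
  expect_error(session_firing_rate(tr, c(10, 5)),
               class = "lfpevents_argument_error")

  fast <- spike_train(seq(0, 100, by = 1 / 12))  # 12 Hz
  expect_true(putative_interneuron(fast, c(0, 100))$putative_interneuron)
  expect_false(putative_interneuron(tr, c(0, 300))$putative_interneuron)
})

test_that("event-triggered rasters equal direct subtraction", {
  tr <- spike_train(seq(0.5, 199.5, by = 1))  # regular 1 Hz spiking
  ev <- regular_events(5, spacing = 30, dur = 0.4, start = 20)
  ras <- event_triggered_raster(tr, ev, window = 5)
  for (i in seq_along(ras)) {
    cc <- ev$center[i]
    direct <- tr$spike_times[abs(tr$spike_times - cc) <= 5] - cc
    expect_equal(ras[[i]], direct)
  }
  # spike exactly at a center maps to relative time 0
  tr0 <- spike_train(c(10.2))
  ras0 <- event_triggered_raster(tr0, data.frame(center = 10.2), window = 5)
  expect_equal(ras0[[1]], 0)
  # a spike 5.1 s away is outside a 5-s window
  tr1 <- spike_train(c(15.3))
  ras1 <- event_triggered_raster(tr1, data.frame(center = 10.2), window = 5)
  expect_length(ras1[[1]], 0L)
})

test_that("PETHs conserve spike counts and expose silenced centers", {
  ev <- regular_events(50, spacing = 20, dur = 1, start = 15)
  tr <- generate_spiketrain(1100, base_rate = 6, suppression = 0,
                            events = ev, seed = 12)
  ras <- event_triggered_raster(tr, ev, window = 5)
  ph <- compute_peth(ras, bin_width = 0.1)
  # conservation: rates * bin width * n_events give back the raster count
  expect_equal(sum(ph$mean_rate) * 0.1 * length(ras), sum(lengths(ras)))
  # central bins (inside the silenced 1-s event span) are at zero
  central <- abs(ph$bin_centers) < 0.4
  expect_true(all(ph$mean_rate[central] == 0))
  # flanking baseline near the base rate
  flank <- abs(ph$bin_centers) > 2
  expect_equal(mean(ph$mean_rate[flank]), 6, tolerance = 0.5)
})

test_that("the PETH of an unmodulated Poisson train is flat", {
  n_ev <- 10000
  ev <- regular_events(n_ev, spacing = 11, dur = 0.4, start = 10)
  dur <- 11 * n_ev + 20
  tr <- generate_spiketrain(dur, base_rate = 2, suppression = 1, seed = 13)
  ph <- compute_peth(event_triggered_raster(tr, ev, window = 5),
                     bin_width = 0.1)
  # per-bin SE of the mean rate across events
  se <- apply(ph$per_event_counts / 0.1, 2, sd) / sqrt(n_ev)
  dev <- abs(ph$mean_rate - 2)
  expect_true(max(dev / se) < 4)
})

test_that("event-locked modulation recovers injected suppression", {
  ev <- regular_events(200, spacing = 10, dur = 0.4, start = 10)
  dur <- 2020
  # full suppression: pct near 0, decisively significant
  tr0 <- generate_spiketrain(dur, base_rate = 5, suppression = 0,
                             events = ev, seed = 14)
  m0 <- event_rate_modulation(tr0, ev)
  expect_equal(m0$pct_of_baseline, 0)
  expect_lt(m0$p_value, 1e-6)
  # graded suppression recovered within +/-10 percentage points
  for (seed in 15:19) {
    tr <- generate_spiketrain(dur, base_rate = 5, suppression = 0.5,
                              events = ev, seed = seed)
    m <- event_rate_modulation(tr, ev)
    expect_lt(abs(m$pct_of_baseline - 50), 10)
    expect_lt(m$p_value, 0.05)
    expect_equal(m$df, m$n_events - 1)
  }
})

test_that("modulation flags zero baselines and requires enough events", {
  ev <- regular_events(5, spacing = 10, dur = 0.4, start = 10)
  silent <- spike_train(ev$onset + 0.1)  # fires only inside events
  m <- event_rate_modulation(silent, ev)
  expect_true(is.na(m$pct_of_baseline))
  expect_equal(m$flag, "zero_baseline")
  expect_error(event_rate_modulation(spike_train(1:10), ev[1, ]),
               class = "lfpevents_argument_error")
})

test_that("group rate comparison has the documented U convention and power", {
  res <- compare_group_rates(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)  # min(U_a, U_b)
  expect_equal(res$p.value, 0.1)
  expect_equal(res$mode, "exact")

  same <- compare_group_rates(c(2, 4, 9, 5), c(2, 4, 9, 5))
  expect_equal(same$z, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1, tolerance = 1e-12)

  # power check at the reference sample sizes: susceptible units firing at
  # 60% of the control rate, n = 15 vs 24, detected in most seeds
  sig <- vapply(1:10, function(s) {
    ctrl <- vapply(1:15, function(i)
      session_firing_rate(generate_spiketrain(300, 5, seed = s * 100 + i),
                          c(0, 300)), numeric(1))
    susc <- vapply(1:24, function(i)
      session_firing_rate(generate_spiketrain(300, 3, seed = s * 100 + 50 + i),
                          c(0, 300)), numeric(1))
    compare_group_rates(ctrl, susc)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.7)
})
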