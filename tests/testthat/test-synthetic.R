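# Synthetic ground-truth generators: reproducibility, the statistical
# contracts (event placement, spike-rate modulation, zone occupancy), and
# cohort assembly.

test_that("generate_lfp is bit-reproducible and honours the zero-rate case", {
  a <- generate_lfp(100, fs = 2000, spec = event_spec(rate = 0.1), seed = 11)
  b <- generate_lfp(100, fs = 2000, spec = event_spec(rate = 0.1), seed = 11)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_lfp(100, fs = 2000, spec = event_spec(rate = 0.1), seed = 12)
  expect_false(identical(a$record$samples, c$record$samples))

  pure <- generate_lfp(30, fs = 2000, spec = event_spec(rate = 0), seed = 1)
  expect_equal(nrow(pure$ground_truth), 0L)
  expect_equal(sd(pure$record$samples), 1, tolerance = 0.05)
})

test_that("generate_lfp validates its arguments", {
  expect_error(generate_lfp(-5, fs = 2000), class = "lfpevents_argument_error")
  expect_error(generate_lfp(10, fs = 100, spec = event_spec()),
               class = "lfpevents_argument_error")  # fs < 4 x band top
  expect_error(event_spec(rate = -1), class = "lfpevents_argument_error")
  expect_error(event_spec(duration_mean = 0), class = "lfpevents_argument_error")
})

test_that("injected bursts never overlap and respect the refractory gap", {
  for (seed in 1:20) {
    sim <- generate_lfp(300, fs = 2000,
                        spec = event_spec(rate = 0.2, refractory = 1),
                        seed = seed)
    gt <- sim$ground_truth
    if (nrow(gt) < 2) next
    expect_true(all(diff(gt$onset) >= 1 - 1e-12))
    expect_true(all(gt$onset[-1] >= gt$offset[-nrow(gt)]))
  }
  # exact-count placement mode
  sim <- burst_record(n_events = 12, duration = 120, seed = 5)
  expect_equal(nrow(sim$ground_truth), 12L)
  expect_true(all(diff(sim$ground_truth$onset) >= 1 - 1e-12))
})

test_that("event counts scale with the configured rate", {
  # rate 0.05 events/s over 600 s should inject about 30 events
  counts <- vapply(1:10, function(s) {
    nrow(generate_lfp(600, fs = 2000, spec = event_spec(rate = 0.05),
                      seed = s)$ground_truth)
  }, numeric(1))
  expect_gt(mean(counts), 30 - 3 * sqrt(30 / 10))
  expect_lt(mean(counts), 30 + 3 * sqrt(30 / 10))
})

test_that("spike trains realize the requested in/out-of-event rates", {
  ev <- regular_events(100, spacing = 19, dur = 0.4)
  # full silencing: no spikes inside the single event
  one <- data.frame(onset = 10, offset = 11)
  tr0 <- generate_spiketrain(60, base_rate = 20, suppression = 0,
                             events = one, seed = 3)
  expect_equal(sum(tr0$spike_times >= 10 & tr0$spike_times <= 11), 0)

  # no modulation: empirical rate near base rate
  tr1 <- generate_spiketrain(2000, base_rate = 5, suppression = 1, seed = 4)
  expect_equal(length(tr1$spike_times) / 2000, 5,
               tolerance = 3 * sqrt(5 / 2000) / 5)

  # Monte-Carlo recovery of suppression 0.5 from in/out rate ratio
  ev <- regular_events(100, spacing = 19.5, dur = 0.4)
  ratios <- vapply(1:10, function(s) {
    tr <- generate_spiketrain(2000, base_rate = 5, suppression = 0.5,
                              events = ev, seed = s)
    st <- tr$spike_times
    inside <- vapply(st, function(t)
      any(t >= ev$onset & t <= ev$offset), logical(1))
    t_in <- sum(ev$offset - ev$onset)
    (sum(inside) / t_in) / (sum(!inside) / (2000 - t_in))
  }, numeric(1))
  expect_true(all(abs(ratios - 0.5) < 0.1))
})

test_that("spike counts match specified rates within 3 binomial SDs", {
  ev <- regular_events(200, spacing = 9.7, dur = 0.5)
  tr <- generate_spiketrain(2000, base_rate = 8, suppression = 0.25,
                            events = ev, seed = 9)
  st <- tr$spike_times
  inside <- vapply(st, function(t) any(t >= ev$onset & t <= ev$offset),
                   logical(1))
  t_in <- sum(ev$offset - ev$onset)
  exp_in <- 8 * 0.25 * t_in
  exp_out <- 8 * (2000 - t_in)
  expect_lt(abs(sum(inside) - exp_in), 3 * sqrt(exp_in))
  expect_lt(abs(sum(!inside) - exp_out), 3 * sqrt(exp_out))
})

test_that("generate_spiketrain rejects invalid suppression and events", {
  expect_error(generate_spiketrain(10, 5, suppression = 1.5),
               class = "lfpevents_argument_error")
  expect_error(generate_spiketrain(10, 5, suppression = 0.5,
                                   events = data.frame(onset = 5, offset = 20)),
               class = "lfpevents_argument_error")
})

test_that("trajectories hit the target zone occupancy to one frame", {
  zone <- interaction_zone()
  trk0 <- generate_trajectory(150, target_occupancy = 0, seed = 1)
  expect_equal(time_in_zone(trk0, zone), 0)
  for (seed in 1:5) {
    trk <- generate_trajectory(150, target_occupancy = 75, seed = seed)
    expect_equal(time_in_zone(trk, zone), 75, tolerance = 1 / 15)
  }
  full <- generate_trajectory(150, target_occupancy = 150, seed = 2)
  expect_equal(time_in_zone(full, zone), 150, tolerance = 1 / 15)
  expect_error(generate_trajectory(150, zone = c(-5, 10, 0, 10),
                                   target_occupancy = 10),
               class = "lfpevents_argument_error")
})

test_that("constructed occupancies give the expected downstream SI ratio", {
  t_no <- generate_trajectory(150, target_occupancy = 60, seed = 21)
  t_tg <- generate_trajectory(150, target_occupancy = 30, seed = 22)
  zone <- interaction_zone()
  res <- si_classify("SD", time_in_zone(t_no, zone), time_in_zone(t_tg, zone))
  expect_equal(res$si_ratio, 0.5, tolerance = 0.01)
  expect_equal(res$group, "susceptible")
})

test_that("generate_cohort writes a complete, reproducible study", {
  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- cohort_config(groups = list(
    control = list(n_mice = 2, event_rate = 0.05,
                   si_occupancy = c(no_target = 30, target = 45)),
    susceptible = list(n_mice = 2, event_rate = 0.02,
                       si_occupancy = c(no_target = 30, target = 15))),
    session_length = 60)
  generate_cohort(cfg, d1, seed = 42)
  generate_cohort(cfg, d2, seed = 42)

  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(file.exists(file.path(d1, "ground_truth.json")))
  mice <- list.dirs(d1, recursive = FALSE)
  expect_length(mice, 4L)
  expect_true(all(file.exists(file.path(mice, "spikes.csv"))))
  expect_true(all(file.exists(file.path(mice, "lfp_ch1.dat"))))

  # byte-identical output under the same config and seed
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  unlink(c(d1, d2), recursive = TRUE)
})
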