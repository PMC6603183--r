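# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no data files are stored.

# A short LFP record with bursts at known positions, for detector tests.
burst_record <- function(duration = 120, n_events = 4, freq = 30,
                         burst_dur = 0.4, amplitude = 10, seed = 1,
                         fs = 2000) {
  generate_lfp(duration, fs = fs,
               spec = event_spec(osc_freq_range = c(freq, freq),
                                 duration_mean = burst_dur, duration_sd = 0,
                                 amplitude = amplitude),
               n_events = n_events, seed = seed)
}

# Do detected events and injected intervals overlap? Returns c(sensitivity
# numerator info): for each truth row, whether any detection overlaps it,
# and for each detection, whether it overlaps any truth row.
overlap_counts <- function(detected, truth) {
  hit_truth <- vapply(seq_len(nrow(truth)), function(i) {
    any(detected$onset < truth$offset[i] & detected$offset > truth$onset[i])
  }, logical(1))
  hit_det <- vapply(seq_len(nrow(detected)), function(i) {
    any(truth$onset < detected$offset[i] & truth$offset > detected$onset[i])
  }, logical(1))
  list(truth_hit = hit_truth, det_hit = hit_det)
}

# Evenly spaced event intervals for spike-train tests.
regular_events <- function(n, spacing = 10, dur = 0.4, start = 10) {
  onset <- start + (seq_len(n) - 1) * spacing
  data.frame(onset = onset, offset = onset + dur,
             center = onset + dur / 2)
}

# Independent brute-force Mann-Whitney oracle: enumerate every assignment
# of the pooled values to group x and count U statistics as or more
# extreme than the observed one (two-tailed as 2 * min tail, capped at 1).
mwu_enumeration_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  u_obs <- min(u_obs, nx * (N - nx) - u_obs)
  combos <- utils::combn(N, nx)
  us <- apply(combos, 2, u_of)
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= nx * (N - nx) - u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}
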