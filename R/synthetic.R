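# Synthetic ground-truth generator: LFP with injected 20-40 Hz bursts,
# Poisson spike trains with event-locked suppression, and arena tracks with
# controlled interaction-zone occupancy. Every downstream stage is validated
# against the ground truth these functions record.

#' Specify injected oscillatory bursts
#'
#' Parameters of the burst population embedded in synthetic LFP by
#' [generate_lfp()]. Defaults reflect the empirical statistics of
#' spontaneous prefrontal 20-40 Hz events: an average rate of 0.05 events/s,
#' durations of a few hundred milliseconds (typically below 0.5 s), and
#' oscillation frequencies spanning the 20-40 Hz band.
#'
#' @param rate expected events per second (Poisson onset rate before
#'   refractory thinning).
#' @param duration_mean,duration_sd burst duration distribution in seconds
#'   (normal, truncated below at the ramp length). Durations refer to the
#'   half-maximum span of the burst envelope.
#' @param osc_freq_range two-element Hz interval from which each burst's
#'   frequency is drawn uniformly.
#' @param amplitude burst peak amplitude as a multiple of the background
#'   noise SD.
#' @param refractory minimum onset-to-onset gap in seconds.
#' @param ramp raised-cosine on/off ramp length in seconds (default 25 ms);
#'   ground-truth onset/offset are the ramp half-maximum points.
#' @return an object of class `event_spec`.
#' @export
event_spec <- function(rate = 0.05, duration_mean = 0.3, duration_sd = 0.1,
                       osc_freq_range = c(20, 40), amplitude = 8,
                       refractory = 1, ramp = 0.025) {
  check_arg(rate >= 0, "'rate' must be >= 0")
  check_arg(duration_mean > 0, "'duration_mean' must be > 0")
  check_arg(duration_sd >= 0, "'duration_sd' must be >= 0")
  check_arg(length(osc_freq_range) == 2L &&
              osc_freq_range[1] > 0 && osc_freq_range[2] >= osc_freq_range[1],
            "'osc_freq_range' must be an ascending positive Hz interval")
  check_arg(amplitude >= 0, "'amplitude' must be >= 0")
  check_arg(refractory >= 0, "'refractory' must be >= 0")
  check_arg(ramp > 0, "'ramp' must be > 0")
  structure(list(rate = rate, duration_mean = duration_mean,
                 duration_sd = duration_sd,
                 osc_freq_range = as.numeric(osc_freq_range),
                 amplitude = amplitude, refractory = refractory, ramp = ramp),
            class = "event_spec")
}

# Draw burst durations: normal truncated below at max(ramp, 0.02 s).
draw_durations <- function(n, spec) {
  pmax(max(spec$ramp, 0.02),
       stats::rnorm(n, spec$duration_mean, spec$duration_sd))
}

# Raised-cosine burst envelope on a sample grid. onset/offset are the
# half-maximum points; the envelope's support extends ramp/2 beyond each.
burst_envelope <- function(t, onset, offset, ramp) {
  env <- numeric(length(t))
  up <- t >= onset - ramp / 2 & t < onset + ramp / 2
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - onset + ramp / 2) / ramp))
  mid <- t >= onset + ramp / 2 & t <= offset - ramp / 2
  env[mid] <- 1
  dn <- t > offset - ramp / 2 & t <= offset + ramp / 2
  env[dn] <- 0.5 * (1 + cos(pi * (t[dn] - offset + ramp / 2) / ramp))
  env
}

# 1/f ("pink") noise with unit SD, via spectral shaping of white noise.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))             # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)               # symmetric over the FFT mirror
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

#' Generate synthetic LFP with injected oscillatory bursts
#'
#' Produces a noise trace with sinusoidal 20-40 Hz bursts added at
#' Poisson-distributed onsets (thinned to respect the refractory gap and to
#' keep bursts non-overlapping), each with raised-cosine on/off ramps and a
#' frequency drawn uniformly from the specified band. The returned ground
#' truth lists every injected burst, which is what detector recovery tests
#' score against.
#'
#' @param duration record length in seconds.
#' @param fs sampling rate in Hz; must be at least 4x the top of
#'   `spec$osc_freq_range`.
#' @param noise_sd background noise SD (signal units).
#' @param spec an [event_spec()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param n_events if given, inject exactly this many bursts at uniform
#'   positions (respecting refractory and non-overlap) instead of a Poisson
#'   count at `spec$rate`.
#' @param noise `"white"` (default) or `"pink"` (1/f) background; detection
#'   thresholds are in z-units of the RMS envelope and so are insensitive
#'   to noise color by construction.
#' @param channel_id,depth,region passed to [lfp_record()].
#' @return list with components `record` (an [lfp_record()]) and
#'   `ground_truth` (data frame: `onset`, `offset`, `duration`, `freq`,
#'   `amplitude`, seconds/Hz/noise-SD units).
#' @examples
#' sim <- generate_lfp(60, fs = 2000, spec = event_spec(rate = 0.1), seed = 1)
#' nrow(sim$ground_truth)
#' @export
generate_lfp <- function(duration, fs = 2000, noise_sd = 1,
                         spec = event_spec(), seed = NULL, n_events = NULL,
                         noise = c("white", "pink"), channel_id = "ch1",
                         depth = 2.3, region = NULL) {
  noise <- match.arg(noise)
  check_arg(duration > 0, "'duration' must be positive")
  check_arg(fs > 0, "'fs' must be positive")
  check_arg(fs >= 4 * max(spec$osc_freq_range),
            sprintf("fs = %g Hz is too low for a %g-Hz band (need >= 4x)",
                    fs, max(spec$osc_freq_range)))
  check_arg(noise_sd >= 0, "'noise_sd' must be >= 0")
  with_seed(seed, {
    n <- round(duration * fs)
    x <- if (noise_sd > 0) {
      if (noise == "white") stats::rnorm(n, sd = noise_sd)
      else noise_sd * pink_noise(n)
    } else numeric(n)
    truth <- place_bursts(duration, spec, n_events)
    if (nrow(truth)) {
      t_all <- (seq_len(n) - 1) / fs
      for (i in seq_len(nrow(truth))) {
        on <- truth$onset[i]; off <- truth$offset[i]
        i0 <- max(1L, floor((on - spec$ramp / 2) * fs) + 1L)
        i1 <- min(n, ceiling((off + spec$ramp / 2) * fs) + 1L)
        idx <- i0:i1
        env <- burst_envelope(t_all[idx], on, off, spec$ramp)
        phase <- stats::runif(1, 0, 2 * pi)
        x[idx] <- x[idx] + spec$amplitude * noise_sd * env *
          sin(2 * pi * truth$freq[i] * t_all[idx] + phase)
      }
    }
    list(record = lfp_record(x, fs, channel_id = channel_id, depth = depth,
                             region = region),
         ground_truth = truth)
  })
}

# Choose burst onsets/durations. Poisson candidates thinned sequentially by
# the refractory and non-overlap constraints, or exactly n bursts placed
# uniformly with minimum gaps via the spacing construction.
place_bursts <- function(duration, spec, n_events = NULL) {
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), freq = numeric(0),
                      amplitude = numeric(0))
  margin <- spec$ramp / 2
  if (is.null(n_events)) {
    if (spec$rate <= 0) return(empty)
    n_cand <- stats::rpois(1, spec$rate * duration)
    if (n_cand == 0) return(empty)
    onsets <- sort(stats::runif(n_cand, 0, duration))
    durs <- draw_durations(n_cand, spec)
    keep <- logical(n_cand)
    last_onset <- -Inf; last_end <- -Inf
    for (i in seq_len(n_cand)) {
      if (onsets[i] - last_onset >= spec$refractory &&
          onsets[i] - margin >= last_end &&
          onsets[i] + durs[i] + margin <= duration) {
        keep[i] <- TRUE
        last_onset <- onsets[i]
        last_end <- onsets[i] + durs[i] + margin
      }
    }
    onsets <- onsets[keep]; durs <- durs[keep]
  } else {
    check_arg(n_events >= 0, "'n_events' must be >= 0")
    if (n_events == 0) return(empty)
    durs <- draw_durations(n_events, spec)
    # required gap between consecutive onsets
    req <- pmax(spec$refractory, durs + 2 * margin)
    need <- sum(req[-n_events]) + durs[n_events] + 2 * margin
    free <- duration - need
    check_arg(free > 0,
              sprintf("cannot place %d bursts with these gaps in %g s",
                      n_events, duration))
    base <- sort(stats::runif(n_events, 0, free))
    onsets <- margin + base + c(0, cumsum(req[-n_events]))
  }
  if (!length(onsets)) return(empty)
  freqs <- stats::runif(length(onsets), spec$osc_freq_range[1],
                        spec$osc_freq_range[2])
  data.frame(onset = onsets, offset = onsets + durs, duration = durs,
             freq = freqs, amplitude = spec$amplitude)
}

#' Generate a Poisson spike train with event-locked suppression
#'
#' Inhomogeneous Poisson process with rate `base_rate` outside the supplied
#' event intervals and `base_rate * suppression` inside them, generated
#' exactly by thinning a homogeneous process at the maximum rate. A
#' suppression of 0 silences the unit during events; 1 leaves it
#' unmodulated.
#'
#' @param duration epoch length in seconds.
#' @param base_rate baseline firing rate in Hz.
#' @param suppression rate multiplier in `[0, 1]` applied inside events.
#' @param events data frame with `onset`/`offset` columns (seconds), or a
#'   two-column matrix; may be empty.
#' @param seed integer seed or `NULL`.
#' @param unit_id,region passed to [spike_train()].
#' @return a [spike_train()].
#' @export
generate_spiketrain <- function(duration, base_rate, suppression = 1,
                                events = NULL, seed = NULL, unit_id = "u1",
                                region = "vmPFC") {
  check_arg(duration > 0, "'duration' must be positive")
  check_arg(base_rate >= 0, "'base_rate' must be >= 0")
  check_arg(suppression >= 0 && suppression <= 1,
            "'suppression' must lie in [0, 1]")
  ev <- normalize_events(events)
  check_arg(!nrow(ev) || (all(ev$onset >= 0) && all(ev$offset <= duration)),
            "'events' must lie within [0, duration]")
  with_seed(seed, {
    if (base_rate == 0) return(spike_train(numeric(0), unit_id, region))
    n <- stats::rpois(1, base_rate * duration)
    cand <- sort(stats::runif(n, 0, duration))
    if (nrow(ev) && suppression < 1) {
      inside <- in_any_interval(cand, ev$onset, ev$offset)
      accept <- !inside | stats::runif(n) < suppression
      cand <- cand[accept]
    }
    spike_train(cand, unit_id, region)
  })
}

# normalize event intervals to a data.frame(onset, offset)
normalize_events <- function(events) {
  if (is.null(events)) return(data.frame(onset = numeric(0), offset = numeric(0)))
  if (is.matrix(events)) events <- data.frame(onset = events[, 1], offset = events[, 2])
  check_arg(all(c("onset", "offset") %in% names(events)),
            "'events' must have 'onset' and 'offset' columns")
  check_arg(!nrow(events) || all(events$offset >= events$onset),
            "event offsets must be >= onsets")
  events[order(events$onset), c("onset", "offset"), drop = FALSE]
}

# vectorized point-in-any-interval test (intervals sorted, non-overlapping)
in_any_interval <- function(t, onset, offset) {
  if (!length(onset)) return(rep(FALSE, length(t)))
  i <- findInterval(t, onset)
  i > 0 & t <= offset[pmax(i, 1L)]
}

#' Generate an arena track with controlled zone occupancy
#'
#' Random-walk trajectory inside a rectangular arena whose realized time in
#' a target zone equals `target_occupancy` to within one frame. The
#' generator schedules the exact number of in-zone frames (split into a few
#' contiguous visits at random positions in the session) and constrains a
#' reflected Gaussian random walk to the scheduled region frame by frame.
#' Kinematic realism is not attempted; the occupancy contract is what
#' downstream analyses consume.
#'
#' @param session_length session duration in seconds.
#' @param arena `c(width, height)` in cm (default the 39.3 x 39.3 cm
#'   square arena of the social-interaction test).
#' @param zone zone rectangle `c(xmin, xmax, ymin, ymax)` in cm; default
#'   the interaction-zone preset [interaction_zone()].
#' @param target_occupancy seconds the track must spend inside `zone`.
#' @param frame_rate frames per second (default 15, the usual video rate).
#' @param seed integer seed or `NULL`.
#' @param step_sd random-walk step SD in cm per frame.
#' @return a [position_track()].
#' @export
generate_trajectory <- function(session_length = 150,
                                arena = c(39.3, 39.3),
                                zone = interaction_zone(arena),
                                target_occupancy = 0,
                                frame_rate = 15, seed = NULL, step_sd = 2) {
  check_arg(session_length > 0, "'session_length' must be positive")
  check_arg(target_occupancy >= 0 && target_occupancy <= session_length,
            "'target_occupancy' must lie in [0, session_length]")
  zone <- as.numeric(zone)
  check_arg(length(zone) == 4L && zone[1] < zone[2] && zone[3] < zone[4],
            "'zone' must be c(xmin, xmax, ymin, ymax) with min < max")
  check_arg(zone[1] >= 0 && zone[2] <= arena[1] &&
              zone[3] >= 0 && zone[4] <= arena[2],
            "'zone' must be contained in the arena")
  with_seed(seed, {
    n <- round(session_length * frame_rate)
    k <- round(target_occupancy * frame_rate)
    k <- min(k, n)
    inzone <- schedule_zone_frames(n, k)
    eps <- 0.05  # cm margin keeping out-frames strictly outside the zone
    x <- numeric(n); y <- numeric(n)
    # start outside the zone when possible
    p <- c(arena[1] / 2, arena[2] - eps)
    if (inzone[1]) p <- c(mean(zone[1:2]), mean(zone[3:4]))
    x[1] <- p[1]; y[1] <- p[2]
    for (i in seq_len(n)[-1]) {
      px <- x[i - 1] + stats::rnorm(1, 0, step_sd)
      py <- y[i - 1] + stats::rnorm(1, 0, step_sd)
      if (inzone[i]) {
        px <- reflect_into(px, zone[1] + eps, zone[2] - eps)
        py <- reflect_into(py, zone[3] + eps, zone[4] - eps)
      } else {
        px <- reflect_into(px, 0, arena[1])
        py <- reflect_into(py, 0, arena[2])
        if (px >= zone[1] && px <= zone[2] && py >= zone[3] && py <= zone[4]) {
          # push out across the nearest zone edge that has room outside it
          # (edges flush with an arena wall cannot be exited through)
          d <- c(px - zone[1], zone[2] - px, py - zone[3], zone[4] - py)
          d[c(zone[1] - eps < 0, zone[2] + eps > arena[1],
              zone[3] - eps < 0, zone[4] + eps > arena[2])] <- Inf
          side <- which.min(d)
          if (side == 1) px <- zone[1] - eps
          else if (side == 2) px <- zone[2] + eps
          else if (side == 3) py <- zone[3] - eps
          else py <- zone[4] + eps
        }
      }
      x[i] <- px; y[i] <- py
    }
    position_track((seq_len(n) - 1) / frame_rate, x, y, frame_rate)
  })
}

# lay out k in-zone frames among n as a few contiguous visits
schedule_zone_frames <- function(n, k) {
  inzone <- rep(FALSE, n)
  if (k == 0) return(inzone)
  if (k >= n) return(rep(TRUE, n))
  n_visits <- max(1L, min(5L, floor(k / 15), floor((n - k) / 15)))
  sizes <- rep(k %/% n_visits, n_visits)
  extra <- k - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  # choose visit start offsets in the out-of-zone remainder
  gaps_total <- n - k
  cuts <- sort(sample.int(gaps_total, n_visits))
  pos <- 1L
  gi <- 0L
  for (v in seq_len(n_visits)) {
    gap <- cuts[v] - gi
    gi <- cuts[v]
    pos <- pos + gap
    inzone[pos:(pos + sizes[v] - 1L)] <- TRUE
    pos <- pos + sizes[v]
  }
  inzone
}

# reflect a scalar coordinate into [lo, hi]
reflect_into <- function(p, lo, hi) {
  if (hi <= lo) return((lo + hi) / 2)
  width <- hi - lo
  p <- (p - lo) %% (2 * width)
  if (p > width) p <- 2 * width - p
  p + lo
}
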