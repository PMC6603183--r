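# Spike-train analyses: session firing rates, event-triggered rasters and
# peri-event time histograms (PETHs), per-cell event-locked modulation
# tests, and group comparisons.

#' Session firing rate
#'
#' Mean firing rate of a unit over an epoch: spike count divided by epoch
#' length.
#'
#' @param train a [spike_train()].
#' @param epoch `c(start, end)` in seconds; defaults to `[0, last spike]`.
#' @return rate in Hz.
#' @export
session_firing_rate <- function(train, epoch = NULL) {
  check_arg(inherits(train, "spike_train"), "'train' must be a spike_train")
  st <- train$spike_times
  epoch <- epoch %||% c(0, if (length(st)) max(st) else 1)
  check_arg(length(epoch) == 2L && epoch[2] > epoch[1],
            "'epoch' must be c(start, end) with end > start")
  sum(st >= epoch[1] & st <= epoch[2]) / (epoch[2] - epoch[1])
}

#' Flag putative interneurons
#'
#' Units with an average firing rate above 10 Hz are conventionally
#' regarded as putative fast-spiking interneurons rather than pyramidal
#' cells. Returns the train with its `putative_interneuron` flag set.
#'
#' @param train a [spike_train()].
#' @param epoch epoch for the rate computation (see
#'   [session_firing_rate()]).
#' @param rate_threshold Hz (default 10).
#' @return the train with `putative_interneuron` filled in.
#' @export
putative_interneuron <- function(train, epoch = NULL, rate_threshold = 10) {
  train$putative_interneuron <-
    session_firing_rate(train, epoch) > rate_threshold
  train
}

#' Event-triggered spike raster
#'
#' For each event, spike times re-referenced to the event center and
#' restricted to `[-window, +window]` (boundaries inclusive).
#'
#' @param train a [spike_train()].
#' @param events events with a `center` column (or `onset`/`offset`, from
#'   which centers are computed).
#' @param window half-width in seconds (default 5).
#' @return an object of class `event_raster`: list of per-event relative
#'   spike-time vectors, with attributes `window` and `centers`.
#' @export
event_triggered_raster <- function(train, events, window = 5) {
  check_arg(inherits(train, "spike_train"), "'train' must be a spike_train")
  check_arg(window > 0, "'window' must be positive")
  centers <- event_centers(events)
  st <- train$spike_times
  # spike times are sorted, so each event's window is a binary-search slice
  rel <- lapply(centers, function(cc) {
    i0 <- findInterval(cc - window, st, left.open = TRUE) + 1L
    i1 <- findInterval(cc + window, st)
    if (i1 < i0) return(numeric(0))
    st[i0:i1] - cc
  })
  structure(rel, class = "event_raster", window = window, centers = centers)
}

event_centers <- function(events) {
  if (!is.null(events$center)) return(as.numeric(events$center))
  check_arg(all(c("onset", "offset") %in% names(events)),
            "'events' must have a 'center' or 'onset'/'offset' columns")
  as.numeric((events$onset + events$offset) / 2)
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster> %d events, +/-%g s window, %d spikes total\n",
              length(x), attr(x, "window"), sum(lengths(x))))
  invisible(x)
}

#' Peri-event time histogram
#'
#' Bins each event's relative spike times, converts counts to rates, and
#' averages across events. Spike counts are conserved:
#' `sum(mean_rate) * bin_width * n_events` equals the total number of
#' raster spikes (up to spikes sitting exactly on the upper window edge,
#' which fall in the last bin).
#'
#' @param raster an [event_triggered_raster()].
#' @param bin_width bin width in seconds (default 0.1, matching the
#'   envelope resolution).
#' @return an object of class `peth`: list with `bin_edges`, `bin_centers`,
#'   `mean_rate` (Hz per bin, averaged over events) and `per_event_counts`
#'   (events x bins matrix).
#' @export
compute_peth <- function(raster, bin_width = 0.1) {
  check_arg(inherits(raster, "event_raster"),
            "'raster' must come from event_triggered_raster()")
  check_arg(bin_width > 0, "'bin_width' must be positive")
  w <- attr(raster, "window")
  edges <- seq(-w, w, by = bin_width)
  if (utils::tail(edges, 1) < w) edges <- c(edges, w)
  nb <- length(edges) - 1L
  counts <- t(vapply(raster, function(r) {
    if (!length(r)) return(integer(nb))
    bin <- findInterval(r, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(bin, nbins = nb)
  }, integer(nb)))
  if (length(raster) == 0L) counts <- matrix(0L, 0L, nb)
  widths <- diff(edges)
  mean_rate <- if (nrow(counts)) colMeans(counts) / widths else rep(0, nb)
  structure(
    list(bin_edges = edges, bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
         mean_rate = mean_rate, per_event_counts = counts,
         bin_width = bin_width),
    class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d events x %d bins (%g s bins over +/-%g s)\n",
              nrow(x$per_event_counts), length(x$mean_rate), x$bin_width,
              max(abs(x$bin_edges))))
  invisible(x)
}

#' @export
plot.peth <- function(x, ...) {
  graphics::plot(x$bin_centers, x$mean_rate, type = "s",
                 xlab = "Time from event center (s)",
                 ylab = "Firing rate (Hz)", ...)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  invisible(x)
}

#' Event-locked firing-rate modulation
#'
#' For each event, computes the unit's firing rate inside the event span
#' (`[onset, offset]`) and in a baseline window relative to the event
#' center (default 1-5 s before it), then compares the paired per-event
#' rates with a two-tailed paired t-test. The headline effect size is the
#' percentage of baseline, `100 * mean(in-event rate) / mean(baseline
#' rate)`.
#'
#' Baseline windows extending before the epoch start are trimmed (and
#' dropped if nothing remains); baseline windows overlapping their own
#' event are trimmed at the event onset. Events whose baseline window
#' overlaps a *neighboring* event are kept by default; set
#' `exclude_overlapping = TRUE` to drop them.
#'
#' @param train a [spike_train()].
#' @param events events with `onset`, `offset` (and optionally `center`)
#'   columns; at least 2 are required for the paired test.
#' @param baseline_window `c(lo, hi)` seconds relative to the event center,
#'   default `c(-5, -1)`.
#' @param epoch recording epoch `c(start, end)`; baseline windows are kept
#'   within it. Defaults to `[0, Inf)`.
#' @param exclude_overlapping drop events whose baseline window intersects
#'   another event?
#' @return an object of class `modulation_result`: list with `unit_id`,
#'   `n_events`, `baseline_rate`, `in_event_rate`, `pct_of_baseline`
#'   (`NA` with `flag = "zero_baseline"` when the baseline mean is 0),
#'   `t_stat`, `df`, `p_value`, and the per-event rate vectors.
#' @export
event_rate_modulation <- function(train, events, baseline_window = c(-5, -1),
                                  epoch = c(0, Inf),
                                  exclude_overlapping = FALSE) {
  check_arg(inherits(train, "spike_train"), "'train' must be a spike_train")
  ev <- as.data.frame(events)
  check_arg(all(c("onset", "offset") %in% names(ev)),
            "'events' must have 'onset' and 'offset' columns")
  check_arg(nrow(ev) >= 2L, "at least 2 events are needed for the paired test")
  check_arg(length(baseline_window) == 2L &&
              baseline_window[1] < baseline_window[2],
            "'baseline_window' must be c(lo, hi) with lo < hi")
  centers <- event_centers(ev)
  b_lo <- pmax(centers + baseline_window[1], epoch[1])
  b_hi <- pmin(centers + baseline_window[2], ev$onset)  # never into own event
  trimmed <- sum(b_hi < centers + baseline_window[2] | b_lo > centers +
                   baseline_window[1])
  if (trimmed > 0) {
    message(sprintf("modulation: trimmed %d baseline window(s) at epoch/event edges",
                    trimmed))
  }
  keep <- b_hi > b_lo
  if (exclude_overlapping && nrow(ev) > 1L) {
    overl <- vapply(seq_len(nrow(ev)), function(i) {
      any(ev$onset[-i] < b_hi[i] & ev$offset[-i] > b_lo[i])
    }, logical(1))
    keep <- keep & !overl
  }
  check_arg(sum(keep) >= 2L, "fewer than 2 events with usable baseline windows")
  ev <- ev[keep, , drop = FALSE]
  b_lo <- b_lo[keep]; b_hi <- b_hi[keep]
  st <- train$spike_times
  count_in <- function(lo, hi) {
    vapply(seq_along(lo), function(i) sum(st >= lo[i] & st <= hi[i]),
           numeric(1))
  }
  in_rate <- count_in(ev$onset, ev$offset) / (ev$offset - ev$onset)
  base_rate <- count_in(b_lo, b_hi) / (b_hi - b_lo)
  tt <- tryCatch(paired_t(in_rate, base_rate), lfpevents_degenerate_error =
                   function(e) NULL)
  mb <- mean(base_rate)
  pct <- if (mb > 0) 100 * mean(in_rate) / mb else NA_real_
  structure(
    list(unit_id = train$unit_id, n_events = nrow(ev),
         baseline_rate = mb, in_event_rate = mean(in_rate),
         pct_of_baseline = pct,
         flag = if (mb > 0) NA_character_ else "zero_baseline",
         t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
         df = if (is.null(tt)) NA_integer_ else unname(tt$parameter),
         p_value = if (is.null(tt)) NA_real_ else tt$p.value,
         per_event_in_rate = in_rate, per_event_baseline_rate = base_rate),
    class = "modulation_result")
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<modulation_result> unit %s: %d events\n", x$unit_id,
              x$n_events))
  cat(sprintf("  baseline %.3g Hz, in-event %.3g Hz (%s%% of baseline)\n",
              x$baseline_rate, x$in_event_rate,
              ifelse(is.na(x$pct_of_baseline), "NA",
                     sprintf("%.1f", x$pct_of_baseline))))
  if (!is.na(x$t_stat)) {
    cat(sprintf("  paired t(%d) = %.3g, p = %.3g\n", x$df, x$t_stat,
                x$p_value))
  }
  invisible(x)
}

#' Compare firing rates between two groups of units
#'
#' Two-tailed Mann-Whitney U test between the per-unit rates of two
#' groups (e.g. control vs stress-susceptible), with tie-corrected
#' variance and continuity correction in normal mode. A thin wrapper over
#' [mann_whitney_u()] so group comparisons share a single implementation.
#'
#' @param rates_a,rates_b numeric vectors of per-unit (or per-electrode)
#'   rates, both non-empty.
#' @param ... passed to [mann_whitney_u()].
#' @return see [mann_whitney_u()].
#' @export
compare_group_rates <- function(rates_a, rates_b, ...) {
  mann_whitney_u(rates_a, rates_b, ...)
}
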