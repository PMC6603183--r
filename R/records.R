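#' Construct an LFP record
#'
#' A single channel's continuous voltage trace at a uniform sampling rate,
#' together with the metadata the analyses need (sampling rate, channel id,
#' electrode depth, region label). When `region` is omitted it is derived
#' from `depth` by the 2-mm rule: sites deeper than 2 mm from the cortical
#' surface are labelled `"vmPFC"`, shallower sites `"dmPFC"`, and records
#' without a depth `"unknown"`.
#'
#' @param samples numeric vector of voltage samples (volts or arbitrary
#'   units; the detection pipeline is amplitude-scale invariant because it
#'   works on z-scored envelopes).
#' @param fs sampling rate in Hz.
#' @param channel_id character scalar identifying the channel.
#' @param depth electrode depth in mm from the cortical surface, or `NA`.
#' @param region one of `"ACC"`, `"dmPFC"`, `"vmPFC"`, `"unknown"`;
#'   defaults to the depth-derived label.
#' @return an object of class `lfp_record`.
#' @examples
#' rec <- lfp_record(rnorm(2000), fs = 2000, depth = 2.3)
#' rec$region
#' @export
lfp_record <- function(samples, fs, channel_id = "ch1", depth = NA_real_,
                       region = NULL) {
  check_arg(is.numeric(samples) && length(samples) >= 1L,
            "'samples' must be a non-empty numeric vector")
  check_arg(is.numeric(fs) && length(fs) == 1L && fs > 0,
            "'fs' must be a single positive number")
  check_arg(all(is.finite(samples)), "'samples' must be finite")
  region <- region %||% depth_to_region(depth)
  check_arg(region %in% c("ACC", "dmPFC", "vmPFC", "unknown"),
            "'region' must be one of ACC, dmPFC, vmPFC, unknown")
  structure(
    list(samples = as.numeric(samples), fs = fs,
         channel_id = as.character(channel_id),
         depth = as.numeric(depth), region = region),
    class = "lfp_record")
}

#' @export
print.lfp_record <- function(x, ...) {
  cat(sprintf("<lfp_record> channel %s (%s, depth %s mm): %d samples @ %g Hz (%.1f s)\n",
              x$channel_id, x$region,
              ifelse(is.na(x$depth), "?", format(x$depth)),
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

# seconds spanned by a record
record_duration <- function(record) length(record$samples) / record$fs

#' Construct a spike train
#'
#' Sorted spike times for one unit, with region metadata and a
#' putative-interneuron flag (units firing above 10 Hz on average are
#' conventionally flagged as putative interneurons; see
#' [putative_interneuron()]).
#'
#' @param spike_times numeric vector of spike times in seconds, ascending.
#' @param unit_id character scalar.
#' @param region region label (see [lfp_record()]).
#' @param putative_interneuron logical flag, `NA` when not yet assessed.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(spike_times, unit_id = "u1", region = "unknown",
                        putative_interneuron = NA) {
  check_arg(is.numeric(spike_times), "'spike_times' must be numeric")
  st <- as.numeric(spike_times)
  check_arg(!is.unsorted(st), "'spike_times' must be sorted ascending")
  structure(
    list(spike_times = st, unit_id = as.character(unit_id),
         region = region,
         putative_interneuron = as.logical(putative_interneuron)),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s (%s): %d spikes", x$unit_id, x$region,
              length(x$spike_times)))
  if (length(x$spike_times))
    cat(sprintf(" over [%.2f, %.2f] s", min(x$spike_times),
                max(x$spike_times)))
  cat("\n")
  invisible(x)
}

#' Construct a position track
#'
#' Timestamped 2-D coordinates of the animal in the arena, sampled
#' uniformly at `frame_rate`.
#'
#' @param times frame times in seconds, ascending and uniform.
#' @param x,y coordinates in cm.
#' @param frame_rate frames per second; defaults to the rate implied by
#'   `times`.
#' @return an object of class `position_track`.
#' @export
position_track <- function(times, x, y, frame_rate = NULL) {
  check_arg(length(times) == length(x) && length(x) == length(y),
            "'times', 'x' and 'y' must have equal length")
  check_arg(length(times) >= 1L, "track must contain at least one frame")
  check_arg(!is.unsorted(times, strictly = TRUE),
            "'times' must be strictly ascending")
  dt <- diff(times)
  if (length(dt)) {
    check_arg(max(abs(dt - mean(dt))) < 1e-6 * max(mean(dt), 1),
              "'times' must be uniformly spaced")
  }
  frame_rate <- frame_rate %||% (if (length(dt)) 1 / mean(dt) else NA_real_)
  structure(
    list(times = as.numeric(times), x = as.numeric(x), y = as.numeric(y),
         frame_rate = frame_rate),
    class = "position_track")
}

#' @export
print.position_track <- function(x, ...) {
  cat(sprintf("<position_track> %d frames @ %g Hz (%.1f s)\n",
              length(x$times), x$frame_rate,
              length(x$times) / x$frame_rate))
  invisible(x)
}
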