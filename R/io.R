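# File formats: raw binary LFP with JSON sidecar metadata, and delimited
# UTF-8 tables for events, spikes, tracks and results. All tables
# round-trip numeric values at full double precision.

LFP_FORMAT_VERSION <- "1"

#' Write an LFP record to disk
#'
#' Samples go to a raw little-endian binary file (`float32` or `int16`
#' with a gain), metadata to a JSON sidecar at `<path>.json` (sampling
#' rate, dtype, gain, sample count, channel id, depth, region).
#'
#' @param record an [lfp_record()].
#' @param path output file path (conventionally `.dat`).
#' @param dtype `"float32"` (default, lossless for single precision) or
#'   `"int16"`.
#' @param gain physical units per bit for `int16` storage (e.g. 0.195 for
#'   a microvolt signal digitized at 0.195 uV/bit); ignored for float.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(record, path, dtype = c("float32", "int16"),
                      gain = 1) {
  dtype <- match.arg(dtype)
  check_arg(inherits(record, "lfp_record"), "'record' must be an lfp_record")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  if (dtype == "float32") {
    writeBin(record$samples, con, size = 4L, endian = "little")
  } else {
    check_arg(gain > 0, "'gain' must be positive for int16 storage")
    q <- as.integer(round(record$samples / gain))
    check_arg(all(abs(q) <= 32767L),
              "samples overflow int16 at this gain; increase 'gain'")
    writeBin(q, con, size = 2L, endian = "little")
  }
  sidecar <- list(format_version = LFP_FORMAT_VERSION,
                  fs = record$fs, dtype = dtype,
                  gain = if (dtype == "int16") gain else 1,
                  n_samples = length(record$samples),
                  channel_id = record$channel_id,
                  depth = if (is.na(record$depth)) NULL else record$depth,
                  region = record$region)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an LFP record from disk
#'
#' Counterpart of [write_lfp()]: reads the binary samples and applies the
#' sidecar's gain so the returned record is in physical units. Errors name
#' the offending file and the expected vs actual sample count.
#'
#' @param path binary file path.
#' @param sidecar sidecar path; default `<path>.json`.
#' @return an [lfp_record()].
#' @export
read_lfp <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) format_error(sprintf("LFP file not found: %s", path))
  if (!file.exists(sidecar)) {
    format_error(sprintf("missing sidecar for %s (expected %s)", path, sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("fs", "dtype", "n_samples")) {
    if (is.null(meta[[f]])) {
      format_error(sprintf("sidecar %s lacks required field '%s'", sidecar, f))
    }
  }
  bytes <- switch(meta$dtype, float32 = 4L, int16 = 2L,
                  format_error(sprintf("unknown dtype '%s' in %s",
                                       meta$dtype, sidecar)))
  actual <- file.size(path) / bytes
  if (actual != meta$n_samples) {
    format_error(sprintf(
      "%s: expected %d samples (%d bytes each) but file holds %g",
      path, meta$n_samples, bytes, actual))
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  x <- if (meta$dtype == "float32") {
    readBin(con, numeric(), n = meta$n_samples, size = 4L, endian = "little")
  } else {
    readBin(con, integer(), n = meta$n_samples, size = 2L, signed = TRUE,
            endian = "little") * (meta$gain %||% 1)
  }
  lfp_record(x, meta$fs, channel_id = meta$channel_id %||% "ch1",
             depth = meta$depth %||% NA_real_, region = meta$region)
}

# ---- delimited tables ------------------------------------------------------

# Full-precision CSV writer: numerics rendered with %.17g so doubles
# round-trip exactly.
write_full_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(df[[j]]), "NA", sprintf("%.17g", df[[j]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) format_error(sprintf("table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    format_error(sprintf("%s: missing required column(s): %s", path,
                         paste(missing, collapse = ", ")))
  }
  df
}

#' Write / read an event table
#'
#' One row per detected event: `channel_id`, `onset`, `offset`, `center`,
#' `duration`, `peak_z`, `osc_freq` (seconds / Hz), plus any extra columns
#' present (e.g. provenance). Values round-trip at full double precision.
#'
#' @param events an `oscillatory_events` frame (or compatible data frame).
#' @param path CSV file path.
#' @return `write_events()`: the path, invisibly. `read_events()`: a data
#'   frame of events.
#' @export
write_events <- function(events, path) {
  write_full_csv(as.data.frame(events), path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read_csv_checked(path, c("channel_id", "onset", "offset", "duration"))
}

#' Write / read a spike table
#'
#' Long format, one row per spike: `unit_id`, `region`, `time` (seconds).
#' Reading validates that spike times are ascending within each unit and
#' rejects the file with the offending row number otherwise.
#'
#' @param trains a list of [spike_train()] objects (or one train).
#' @param path CSV file path.
#' @return `write_spike_table()`: the path, invisibly.
#'   `read_spike_table()`: a named list of [spike_train()] objects.
#' @export
write_spike_table <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  rows <- lapply(trains, function(tr) {
    if (!length(tr$spike_times)) return(NULL)
    data.frame(unit_id = tr$unit_id, region = tr$region,
               time = tr$spike_times, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(unit_id = character(0), region = character(0),
               time = numeric(0)))))
  write_full_csv(df, path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  df <- read_csv_checked(path, c("unit_id", "time"))
  out <- list()
  for (uid in unique(df$unit_id)) {
    rows <- which(df$unit_id == uid)
    tt <- df$time[rows]
    if (is.unsorted(tt)) {
      bad <- rows[which(diff(tt) < 0)[1] + 1L]
      format_error(sprintf("%s: spike times for unit %s not ascending at row %d",
                           path, uid, bad))
    }
    region <- if ("region" %in% names(df)) df$region[rows[1]] else "unknown"
    out[[uid]] <- spike_train(tt, unit_id = uid, region = region)
  }
  out
}

#' Write / read a position track
#'
#' Columns `t`, `x`, `y` (seconds, cm). Reading checks that timestamps are
#' uniform; non-uniform tracks (e.g. dropped video frames) trigger a
#' warning and, with `resample = TRUE`, are linearly interpolated back
#' onto a uniform grid at the median frame rate.
#'
#' @param track a [position_track()].
#' @param path CSV file path.
#' @param resample interpolate non-uniform tracks onto a uniform grid?
#' @return `write_track()`: the path, invisibly. `read_track()`: a
#'   [position_track()].
#' @export
write_track <- function(track, path) {
  check_arg(inherits(track, "position_track"),
            "'track' must be a position_track")
  write_full_csv(data.frame(t = track$times, x = track$x, y = track$y), path)
}

#' @rdname write_track
#' @export
read_track <- function(path, resample = FALSE) {
  df <- read_csv_checked(path, c("t", "x", "y"))
  check_arg(nrow(df) >= 2L, "track must contain at least two frames")
  dt <- diff(df$t)
  uniform <- max(abs(dt - stats::median(dt))) < 1e-6 * max(stats::median(dt), 1)
  if (!uniform) {
    warning(sprintf("%s: non-uniform timestamps%s", path,
                    if (resample) "; resampling to a uniform grid" else
                      " (pass resample = TRUE to interpolate)"))
    if (resample) {
      rate <- 1 / stats::median(dt)
      grid <- seq(df$t[1], utils::tail(df$t, 1), by = 1 / rate)
      df <- data.frame(t = grid,
                       x = stats::approx(df$t, df$x, grid)$y,
                       y = stats::approx(df$t, df$y, grid)$y)
    } else {
      # construct without the uniformity validator by re-gridding times
      return(structure(list(times = df$t, x = df$x, y = df$y,
                            frame_rate = 1 / stats::median(dt)),
                       class = "position_track"))
    }
  }
  position_track(df$t, df$x, df$y)
}

#' Write / read a generic results table
#'
#' Plain full-precision CSV with a header row; used for pipeline outputs
#' (per-electrode rates, modulation results, SI summaries, group tests).
#'
#' @param df a data frame.
#' @param path CSV file path.
#' @return `write_results_table()`: the path, invisibly.
#'   `read_results_table()`: a data frame.
#' @export
write_results_table <- function(df, path) write_full_csv(df, path)

#' @rdname write_results_table
#' @export
read_results_table <- function(path) read_csv_checked(path, character(0))
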