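# Social-interaction-test quantification: interaction-zone occupancy,
# SI ratio and susceptible/resilient classification, and locomotion speed.

#' Interaction-zone preset
#'
#' The standard interaction zone of the social-interaction test: a
#' 14.5 cm x 26 cm rectangle extending 8 cm around a 6.5 cm x 10 cm mesh
#' cage centered against one wall of a 39.3 cm x 39.3 cm arena. The cage
#' wall is taken as `y = 0`.
#'
#' @param arena `c(width, height)` in cm.
#' @param cage_width,cage_depth mesh-cage footprint along / away from the
#'   wall, cm.
#' @param margin zone extension around the cage, cm.
#' @return zone rectangle `c(xmin, xmax, ymin, ymax)` in cm.
#' @export
interaction_zone <- function(arena = c(39.3, 39.3), cage_width = 10,
                             cage_depth = 6.5, margin = 8) {
  half <- (cage_width + 2 * margin) / 2
  c(xmin = arena[1] / 2 - half, xmax = arena[1] / 2 + half,
    ymin = 0, ymax = cage_depth + margin)
}

#' Time spent inside a zone
#'
#' Occupancy by frame counting at the track's native frame rate: the
#' number of frames whose position falls inside the rectangle (boundary
#' inclusive: a point exactly on the zone edge counts as inside) divided
#' by the frame rate.
#'
#' @param track a [position_track()].
#' @param zone rectangle `c(xmin, xmax, ymin, ymax)` in cm.
#' @return seconds inside the zone.
#' @export
time_in_zone <- function(track, zone) {
  check_arg(inherits(track, "position_track"),
            "'track' must be a position_track")
  zone <- as.numeric(zone)
  check_arg(length(zone) == 4L && zone[1] <= zone[2] && zone[3] <= zone[4],
            "'zone' must be c(xmin, xmax, ymin, ymax)")
  inside <- track$x >= zone[1] & track$x <= zone[2] &
    track$y >= zone[3] & track$y <= zone[4]
  sum(inside) / track$frame_rate
}

#' Social-interaction classification
#'
#' Computes the SI ratio (interaction-zone time with the target present
#' divided by time with no target) and classifies the mouse:
#' defeated (`"SD"`) mice with ratio < 1 are stress-susceptible and with
#' ratio > 1 stress-resilient; non-defeated (`"non-SD"`) mice with
#' ratio > 1 are controls and are otherwise excluded from analysis. A
#' ratio of exactly 1 falls between the susceptible and resilient
#' definitions; such SD mice receive the distinct label `"boundary"`
#' rather than being forced onto either side.
#'
#' @param sd_status `"SD"` or `"non-SD"`.
#' @param time_no_target,time_target seconds in the interaction zone in
#'   the no-target and target sessions; `time_no_target` must be positive.
#' @return an object of class `si_result`: list with `time_no_target`,
#'   `time_target`, `si_ratio` and `group` (one of `"control"`,
#'   `"susceptible"`, `"resilient"`, `"boundary"`, `"excluded"`).
#' @examples
#' si_classify("SD", time_no_target = 60, time_target = 30)$group
#' @export
si_classify <- function(sd_status = c("SD", "non-SD"), time_no_target,
                        time_target) {
  sd_status <- match.arg(sd_status)
  check_arg(is.numeric(time_no_target) && time_no_target > 0,
            "'time_no_target' must be positive (SI ratio undefined otherwise)")
  check_arg(is.numeric(time_target) && time_target >= 0,
            "'time_target' must be >= 0")
  ratio <- time_target / time_no_target
  group <- if (sd_status == "SD") {
    if (ratio < 1) "susceptible" else if (ratio > 1) "resilient" else "boundary"
  } else {
    if (ratio > 1) "control" else "excluded"
  }
  structure(
    list(sd_status = sd_status, time_no_target = time_no_target,
         time_target = time_target, si_ratio = ratio, group = group),
    class = "si_result")
}

#' @export
print.si_result <- function(x, ...) {
  cat(sprintf("<si_result> %s mouse: IZ %.1f s (no target) / %.1f s (target), SI ratio %.3g -> %s\n",
              x$sd_status, x$time_no_target, x$time_target, x$si_ratio,
              x$group))
  invisible(x)
}

#' Instantaneous locomotion speed
#'
#' Decimates the track to `target_rate` (keeping every
#' `frame_rate / target_rate`-th frame, starting with the first) and
#' computes the speed of each decimated frame as the Euclidean distance
#' travelled since the previous decimated frame divided by the frame
#' interval (~333 ms at the default 3 Hz). The first decimated frame has
#' no predecessor and is dropped.
#'
#' @param track a [position_track()].
#' @param target_rate decimated frame rate in Hz (default 3); must divide
#'   the track's frame rate and not exceed it.
#' @return data frame with `time` (s) and `speed` (cm/s) columns.
#' @export
instantaneous_speed <- function(track, target_rate = 3) {
  check_arg(inherits(track, "position_track"),
            "'track' must be a position_track")
  check_arg(is.numeric(target_rate) && target_rate > 0,
            "'target_rate' must be positive")
  check_arg(target_rate <= track$frame_rate,
            "'target_rate' must not exceed the track frame rate")
  dec <- track$frame_rate / target_rate
  check_arg(abs(dec - round(dec)) < 1e-6,
            "'target_rate' must divide the track frame rate")
  idx <- seq(1L, length(track$times), by = round(dec))
  dx <- diff(track$x[idx]); dy <- diff(track$y[idx])
  speed <- sqrt(dx^2 + dy^2) * target_rate
  data.frame(time = track$times[idx][-1], speed = speed)
}
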