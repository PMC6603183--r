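# Synthetic cohort generation: a complete study on disk (LFP binaries,
# spike tables, tracks, manifest and ground truth) with configurable
# group-level differences, so the full pipeline can be exercised end to
# end against known truth.

#' Cohort configuration
#'
#' Declares the synthetic study design consumed by [generate_cohort()].
#' Defaults mirror the conditions the analyses are built for: 300-s
#' recording sessions at 2 kHz (the two 150-s social-interaction sessions
#' back to back), a control group generating 20-40 Hz events at 0.05
#' events/s versus a susceptible group at a reduced rate, bursts about
#' 0.3 s long at 10x the noise SD, units firing at 5 Hz baseline with half
#' of them suppressed to 50% during events, and interaction-zone
#' occupancies giving controls an SI ratio above 1 and susceptible mice a
#' ratio below 1.
#'
#' @param groups named list; each entry has `n_mice`, `event_rate`
#'   (events/s), and `si_occupancy` (named `c(no_target, target)` seconds
#'   in the interaction zone per 150-s session). Group names `control`
#'   (non-defeated) and `susceptible`/`resilient` (defeated) map onto SD
#'   status automatically.
#' @param channels_per_mouse LFP channels per mouse (vmPFC depths).
#' @param units_per_channel spike-sorted units per channel.
#' @param session_length ephys session length, seconds.
#' @param fs LFP sampling rate, Hz.
#' @param si_session_length length of each SI session, seconds.
#' @param frame_rate video tracking rate, Hz.
#' @param burst burst parameters shared by all groups except the rate: a
#'   list with any of [event_spec()]'s fields.
#' @param base_rate unit baseline firing rate, Hz.
#' @param suppression in-event rate multiplier for modulated units.
#' @param prop_modulated fraction of units that are event-modulated.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(groups = list(
                            control = list(n_mice = 2, event_rate = 0.05,
                                           si_occupancy = c(no_target = 30,
                                                            target = 45)),
                            susceptible = list(n_mice = 2, event_rate = 0.02,
                                               si_occupancy = c(no_target = 30,
                                                                target = 15))),
                          channels_per_mouse = 1, units_per_channel = 2,
                          session_length = 300, fs = 2000,
                          si_session_length = 150, frame_rate = 15,
                          burst = list(amplitude = 10, duration_mean = 0.3,
                                       duration_sd = 0.05),
                          base_rate = 5, suppression = 0.5,
                          prop_modulated = 0.5) {
  check_arg(length(groups) >= 1L && !is.null(names(groups)),
            "'groups' must be a named list")
  for (g in groups) {
    check_arg(all(c("n_mice", "event_rate") %in% names(g)),
              "each group needs 'n_mice' and 'event_rate'")
  }
  structure(list(groups = groups, channels_per_mouse = channels_per_mouse,
                 units_per_channel = units_per_channel,
                 session_length = session_length, fs = fs,
                 si_session_length = si_session_length,
                 frame_rate = frame_rate, burst = burst,
                 base_rate = base_rate, suppression = suppression,
                 prop_modulated = prop_modulated),
            class = "cohort_config")
}

group_sd_status <- function(group) {
  if (group %in% c("susceptible", "resilient")) "SD" else "non-SD"
}

#' Generate a synthetic cohort on disk
#'
#' Writes one directory per mouse (LFP binary + sidecar per channel, a
#' spike table, and no-target/target session tracks) plus a cohort
#' `manifest.json` (design, file inventory, seed) and a
#' `ground_truth.json` recording every injected event, each unit's
#' suppression factor, and the scheduled zone occupancies. Runs are
#' bit-reproducible: the same config and seed give byte-identical files.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the whole cohort.
#' @return the path to `manifest.json`, invisibly.
#' @export
generate_cohort <- function(config = cohort_config(), out_dir, seed = 1) {
  check_arg(inherits(config, "cohort_config"),
            "'config' must come from cohort_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(errorCondition(sprintf("cannot create output directory %s", out_dir),
                        class = c("lfpevents_io_error", "error")))
  }
  manifest <- list(format_version = LFP_FORMAT_VERSION, seed = seed,
                   session_length = config$session_length,
                   si_session_length = config$si_session_length,
                   fs = config$fs, frame_rate = config$frame_rate,
                   zone = as.list(interaction_zone()), mice = list())
  truth <- list(seed = seed, channels = list(), units = list(),
                occupancy = list())
  with_seed(seed, {
    midx <- 0L
    for (gname in names(config$groups)) {
      g <- config$groups[[gname]]
      spec_args <- utils::modifyList(
        list(rate = g$event_rate), config$burst)
      spec <- do.call(event_spec, spec_args)
      for (i in seq_len(g$n_mice)) {
        midx <- midx + 1L
        mouse_id <- sprintf("m%02d", midx)
        mdir <- file.path(out_dir, mouse_id)
        dir.create(mdir, showWarnings = FALSE)
        channels <- list()
        trains <- list()
        units_meta <- list()
        for (ch in seq_len(config$channels_per_mouse)) {
          channel_id <- sprintf("%s_ch%d", mouse_id, ch)
          sim <- generate_lfp(config$session_length, fs = config$fs,
                              spec = spec, channel_id = channel_id,
                              depth = 2.2 + 0.1 * ch)
          fname <- sprintf("lfp_ch%d.dat", ch)
          write_lfp(sim$record, file.path(mdir, fname))
          channels[[length(channels) + 1L]] <- list(
            file = file.path(mouse_id, fname), channel_id = channel_id,
            depth = sim$record$depth, region = sim$record$region)
          truth$channels[[channel_id]] <- sim$ground_truth
          for (u in seq_len(config$units_per_channel)) {
            unit_id <- sprintf("%s_u%d", channel_id, u)
            modulated <- u <= round(config$prop_modulated *
                                      config$units_per_channel)
            supp <- if (modulated) config$suppression else 1
            tr <- generate_spiketrain(config$session_length,
                                      base_rate = config$base_rate,
                                      suppression = supp,
                                      events = sim$ground_truth,
                                      unit_id = unit_id,
                                      region = sim$record$region)
            trains[[length(trains) + 1L]] <- tr
            units_meta[[length(units_meta) + 1L]] <- list(
              unit_id = unit_id, channel_id = channel_id,
              region = sim$record$region)
            truth$units[[unit_id]] <- list(suppression = supp)
          }
        }
        write_spike_table(trains, file.path(mdir, "spikes.csv"))
        occ <- g$si_occupancy %||% c(no_target = 30, target = 30)
        for (sess in c("no_target", "target")) {
          trk <- generate_trajectory(config$si_session_length,
                                     target_occupancy = occ[[sess]],
                                     frame_rate = config$frame_rate)
          write_track(trk, file.path(mdir, sprintf("track_%s.csv", sess)))
        }
        truth$occupancy[[mouse_id]] <- as.list(occ)
        manifest$mice[[length(manifest$mice) + 1L]] <- list(
          mouse_id = mouse_id, group = gname,
          sd_status = group_sd_status(gname),
          channels = channels, units = units_meta,
          tracks = list(no_target = file.path(mouse_id, "track_no_target.csv"),
                        target = file.path(mouse_id, "track_target.csv")),
          spikes = file.path(mouse_id, "spikes.csv"))
      }
    }
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(file.path(out_dir, "manifest.json"))
}
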