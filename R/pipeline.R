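# End-to-end analysis pipeline over a cohort on disk: event detection per
# electrode, threshold sweep, per-unit modulation and PETHs, SI
# classification, and group-level comparisons, all written as
# full-precision tables with provenance columns plus a JSON run manifest.

#' Run the full analysis pipeline
#'
#' Reads a cohort directory (as written by [generate_cohort()], or any
#' dataset with the same manifest layout), runs every analysis stage, and
#' writes the results tree to `out_dir`:
#'
#' * `events.csv` — all detected events with mouse/channel provenance
#' * `electrode_rates.csv` — per-electrode event rate
#' * `threshold_sweep.csv` — event rate per electrode per threshold
#' * `modulation.csv` — per-unit event-locked modulation results
#' * `peth.csv` — per-unit PETH (long format)
#' * `si_summary.csv` — per-mouse zone occupancies, SI ratio, group
#' * `group_tests.csv` — between-group Mann-Whitney tests on event and
#'   firing rates
#' * `prepost_test.csv` — paired pre/post test, when `post_dataset` given
#' * `run_manifest.json` — seed, parameters, parameter hash, package
#'   version
#'
#' Outputs are a deterministic function of (dataset, config): rerunning
#' with the same inputs reproduces every table byte for byte. Any stage
#' failure aborts with the stage name attached.
#'
#' @param config a named list, or a path to a YAML/JSON file containing
#'   one. Recognized fields (all optional except `dataset`):
#'   `dataset` (cohort directory), `out_dir` (default
#'   `file.path(dataset, "results")`), `detection` (arguments for
#'   [detection_params()]), `sweep_thresholds` (default `seq(3, 6, 0.5)`),
#'   `peth` (`window`, `bin_width`), `modulation` (`baseline_window`,
#'   `min_baseline_rate`, default 0.5 Hz inclusion threshold),
#'   `compare_groups` (character pair, default the first two groups
#'   present), and `post_dataset` (a second cohort directory whose
#'   electrodes pair with the first, e.g. post-treatment sessions; event
#'   rates are then compared with a paired t-test).
#' @return the output directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  check_arg(is.list(config) && !is.null(config$dataset),
            "'config' must be a list (or config file) with a 'dataset' field")
  dataset <- config$dataset
  out_dir <- config$out_dir %||% file.path(dataset, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  det <- do.call(detection_params, config$detection %||% list())
  sweep_th <- config$sweep_thresholds %||% seq(3, 6, by = 0.5)
  peth_cfg <- utils::modifyList(list(window = 5, bin_width = 0.1),
                                config$peth %||% list())
  mod_cfg <- utils::modifyList(list(baseline_window = c(-5, -1),
                                    min_baseline_rate = 0.5),
                               config$modulation %||% list())
  phash <- hash_params(list(det = det, sweep = sweep_th, peth = peth_cfg,
                            mod = mod_cfg))

  manifest <- run_stage("read_manifest", read_manifest(dataset))
  primary <- run_stage("detect", pipeline_detect(dataset, manifest, det,
                                                 sweep_th, phash))
  write_events(primary$events, file.path(out_dir, "events.csv"))
  write_results_table(primary$rates, file.path(out_dir, "electrode_rates.csv"))
  write_results_table(primary$sweep, file.path(out_dir, "threshold_sweep.csv"))

  spk <- run_stage("modulation",
                   pipeline_modulation(dataset, manifest, primary$events_by_channel,
                                       peth_cfg, mod_cfg, phash))
  write_results_table(spk$modulation, file.path(out_dir, "modulation.csv"))
  write_results_table(spk$peth, file.path(out_dir, "peth.csv"))

  si <- run_stage("si", pipeline_si(dataset, manifest, phash))
  write_results_table(si, file.path(out_dir, "si_summary.csv"))

  gt <- run_stage("group_tests",
                  pipeline_group_tests(primary$rates, spk$unit_rates,
                                       config$compare_groups, phash))
  write_results_table(gt, file.path(out_dir, "group_tests.csv"))

  if (!is.null(config$post_dataset)) {
    pp <- run_stage("prepost",
                    pipeline_prepost(primary$rates, config$post_dataset,
                                     det, phash))
    write_results_table(pp, file.path(out_dir, "prepost_test.csv"))
  }

  run_manifest <- list(
    dataset = dataset, seed = manifest$seed,
    detection = unclass(det), sweep_thresholds = sweep_th,
    peth = peth_cfg, modulation = mod_cfg, params_hash = phash,
    package_version = as.character(utils::packageVersion("lfpevents")))
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

read_config <- function(path) {
  if (!file.exists(path)) format_error(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

read_manifest <- function(dataset) {
  path <- file.path(dataset, "manifest.json")
  if (!file.exists(path)) format_error(sprintf("no manifest.json in %s", dataset))
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# attach the failing stage's name to any error it raises
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("lfpevents_pipeline_error", "error")))
  })
}

pipeline_detect <- function(dataset, manifest, det, sweep_th, phash) {
  events_rows <- list(); rate_rows <- list(); sweep_rows <- list()
  events_by_channel <- list()
  for (mouse in manifest$mice) {
    for (ch in mouse$channels) {
      rec <- read_lfp(file.path(dataset, ch$file))
      ev <- detect_events(rec, det)
      events_by_channel[[ch$channel_id]] <- ev
      dur <- attr(ev, "analyzed_duration")
      if (nrow(ev)) {
        events_rows[[length(events_rows) + 1L]] <-
          cbind(data.frame(mouse = mouse$mouse_id, group = mouse$group),
                as.data.frame(ev), params_hash = phash)
      }
      rate_rows[[length(rate_rows) + 1L]] <- data.frame(
        mouse = mouse$mouse_id, group = mouse$group,
        channel_id = ch$channel_id, region = ch$region,
        n_events = nrow(ev), analyzed_duration = dur,
        rate = event_rate(ev, dur), params_hash = phash)
      sw <- threshold_sweep(rec, sweep_th, det)
      sweep_rows[[length(sweep_rows) + 1L]] <- cbind(
        data.frame(mouse = mouse$mouse_id, group = mouse$group,
                   channel_id = ch$channel_id), sw, params_hash = phash)
    }
  }
  empty_ev <- data.frame(mouse = character(0), group = character(0),
                         channel_id = character(0), onset = numeric(0),
                         offset = numeric(0), center = numeric(0),
                         duration = numeric(0), peak_z = numeric(0),
                         osc_freq = numeric(0), params_hash = character(0))
  list(events = if (length(events_rows)) do.call(rbind, events_rows) else empty_ev,
       rates = do.call(rbind, rate_rows),
       sweep = do.call(rbind, sweep_rows),
       events_by_channel = events_by_channel)
}

pipeline_modulation <- function(dataset, manifest, events_by_channel,
                                peth_cfg, mod_cfg, phash) {
  mod_rows <- list(); peth_rows <- list(); unit_rows <- list()
  for (mouse in manifest$mice) {
    trains <- read_spike_table(file.path(dataset, mouse$spikes))
    for (um in mouse$units) {
      tr <- trains[[um$unit_id]]
      if (is.null(tr)) next
      epoch <- c(0, manifest$session_length)
      rate <- session_firing_rate(tr, epoch)
      unit_rows[[length(unit_rows) + 1L]] <- data.frame(
        mouse = mouse$mouse_id, group = mouse$group, unit_id = um$unit_id,
        region = um$region, firing_rate = rate,
        putative_interneuron = rate > 10, params_hash = phash)
      ev <- events_by_channel[[um$channel_id]]
      if (is.null(ev) || nrow(ev) < 2L) next
      res <- suppressMessages(
        event_rate_modulation(tr, ev, baseline_window = mod_cfg$baseline_window,
                              epoch = epoch))
      mod_rows[[length(mod_rows) + 1L]] <- data.frame(
        mouse = mouse$mouse_id, group = mouse$group, unit_id = um$unit_id,
        region = um$region, n_events = res$n_events,
        baseline_rate = res$baseline_rate,
        in_event_rate = res$in_event_rate,
        pct_of_baseline = res$pct_of_baseline,
        t_stat = res$t_stat, df = res$df, p_value = res$p_value,
        included = res$baseline_rate > mod_cfg$min_baseline_rate,
        params_hash = phash)
      raster <- event_triggered_raster(tr, ev, window = peth_cfg$window)
      ph <- compute_peth(raster, bin_width = peth_cfg$bin_width)
      peth_rows[[length(peth_rows) + 1L]] <- data.frame(
        mouse = mouse$mouse_id, unit_id = um$unit_id,
        bin_center = ph$bin_centers, mean_rate = ph$mean_rate,
        params_hash = phash)
    }
  }
  empty <- function(...) data.frame(...)
  list(modulation = if (length(mod_rows)) do.call(rbind, mod_rows) else
         empty(mouse = character(0), unit_id = character(0)),
       peth = if (length(peth_rows)) do.call(rbind, peth_rows) else
         empty(mouse = character(0), unit_id = character(0)),
       unit_rates = if (length(unit_rows)) do.call(rbind, unit_rows) else
         empty(mouse = character(0), unit_id = character(0)))
}

pipeline_si <- function(dataset, manifest, phash) {
  zone <- unlist(manifest$zone)
  rows <- lapply(manifest$mice, function(mouse) {
    t_no <- time_in_zone(read_track(file.path(dataset, mouse$tracks$no_target)),
                         zone)
    t_tg <- time_in_zone(read_track(file.path(dataset, mouse$tracks$target)),
                         zone)
    res <- si_classify(mouse$sd_status, t_no, t_tg)
    data.frame(mouse = mouse$mouse_id, design_group = mouse$group,
               sd_status = mouse$sd_status, time_no_target = t_no,
               time_target = t_tg, si_ratio = res$si_ratio,
               si_group = res$group, params_hash = phash)
  })
  do.call(rbind, rows)
}

pipeline_group_tests <- function(rates, unit_rates, compare_groups, phash) {
  groups <- unique(rates$group)
  if (is.null(compare_groups)) compare_groups <- utils::head(groups, 2)
  rows <- list()
  if (length(compare_groups) == 2L && all(compare_groups %in% groups)) {
    a <- rates$rate[rates$group == compare_groups[1]]
    b <- rates$rate[rates$group == compare_groups[2]]
    tst <- compare_group_rates(a, b)
    rows[[1]] <- data.frame(
      measure = "event_rate", group_a = compare_groups[1],
      group_b = compare_groups[2], n_a = length(a), n_b = length(b),
      U = unname(tst$statistic), Z = tst$z, p = tst$p.value,
      method = tst$mode, params_hash = phash)
    if (nrow(unit_rates)) {
      fa <- unit_rates$firing_rate[unit_rates$group == compare_groups[1]]
      fb <- unit_rates$firing_rate[unit_rates$group == compare_groups[2]]
      if (length(fa) && length(fb)) {
        tst2 <- compare_group_rates(fa, fb)
        rows[[2]] <- data.frame(
          measure = "firing_rate", group_a = compare_groups[1],
          group_b = compare_groups[2], n_a = length(fa), n_b = length(fb),
          U = unname(tst2$statistic), Z = tst2$z, p = tst2$p.value,
          method = tst2$mode, params_hash = phash)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(measure = character(0), group_a = character(0)))
  }
  do.call(rbind, rows)
}

pipeline_prepost <- function(pre_rates, post_dataset, det, phash) {
  post_manifest <- read_manifest(post_dataset)
  post <- pipeline_detect(post_dataset, post_manifest, det,
                          seq(3, 6, by = 0.5), phash)$rates
  common <- intersect(pre_rates$channel_id, post$channel_id)
  check_arg(length(common) >= 2L,
            "pre/post comparison needs >= 2 shared electrodes")
  pre_v <- pre_rates$rate[match(common, pre_rates$channel_id)]
  post_v <- post$rate[match(common, post$channel_id)]
  tst <- paired_t(post_v, pre_v)
  data.frame(measure = "event_rate_prepost", n_electrodes = length(common),
             mean_pre = mean(pre_v), mean_post = mean(post_v),
             t_stat = unname(tst$statistic), df = unname(tst$parameter),
             p = tst$p.value, params_hash = phash)
}
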