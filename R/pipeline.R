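#' Pipeline configuration
#'
#' A nested configuration with one section per stage (`simulate`, `detect`,
#' `track`, `events`) plus global fields `seed`, `out_dir` and `log_level`.
#' Every parameter has a default; unknown keys are rejected. Sections map
#' directly onto [sim_config()], [preprocess_params()], [link_params()] and
#' [phase_boundaries()] arguments.
#'
#' @param config named list, or path to a YAML file with the same shape.
#' @param seed optional global seed overriding the config seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  top_known <- c("simulate", "detect", "track", "events", "seed",
                 "out_dir", "log_level")
  unknown <- setdiff(names(config), top_known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  check_section <- function(sec, fn) {
    extra <- setdiff(names(config[[sec]]), names(formals(fn)))
    if (length(extra) > 0L)
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "))
    config[[sec]] %||% list()
  }
  sim_args <- check_section("simulate", sim_config)
  det_args <- check_section("detect", preprocess_params)
  trk_args <- check_section("track", link_params)
  ev_args <- check_section("events", phase_boundaries)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  sim_args$seed <- seed
  structure(list(
    simulate = do.call(sim_config, sim_args),
    detect = do.call(preprocess_params, det_args),
    track = do.call(link_params, trk_args),
    events = do.call(phase_boundaries, ev_args),
    seed = seed,
    out_dir = config$out_dir %||% "trenchlapse_out",
    log_level = config$log_level %||% "info"
  ), class = "pipeline_config")
}

# Tiny FNV-1a hash of a string, for the run manifest.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((bitwXor(as.integer(h %% 2^31), b)) *
                                  16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full simulate-detect-track-events-analyze pipeline
#'
#' Executes every stage on a simulated movie, writes all intermediate
#' artifacts (`phase.tif`, `fluor.tif`, `trench_mask.tif`,
#' `truth_events.csv`, `truth_positions.csv`, `detections.csv`,
#' `tracks.csv`, `events.csv`, `analysis.json`, diagnostic plots) into the
#' output directory together with a run manifest recording the seed, every
#' parameter used and a config hash. Identical configurations and seeds
#' yield identical manifests and event tables.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param out_dir output directory (overrides the config).
#' @param write_movies logical; write the TIFF stacks (default `TRUE`).
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         write_movies = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out <- out_dir %||% config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$simulate
  say <- function(...) if (config$log_level != "quiet")
    message(sprintf(...))

  say("simulating %d trenches for %g h ...", cfg$n_trenches, cfg$duration)
  events <- simulate_lineages(cfg)
  movie <- render_movie(events, cfg)
  truth_ev <- events
  truth_ev$division_time[!is.na(truth_ev$division_time) &
                           truth_ev$division_time > cfg$duration] <- NA
  write_table_csv(truth_ev, file.path(out, "truth_events.csv"))
  write_table_csv(movie$truth_positions,
                  file.path(out, "truth_positions.csv"))
  if (write_movies) {
    write_stack(movie$phase, file.path(out, "phase.tif"))
    write_stack(movie$fluor, file.path(out, "fluor.tif"))
    write_mask(movie$trench_mask, file.path(out, "trench_mask.tif"))
  }

  say("detecting cells in %d phase frames ...", length(movie$phase))
  tm <- label_trenches(movie$trench_mask)
  dets_p <- assign_detections(detect_cells(movie$phase, config$detect), tm)
  dets_f <- assign_detections(
    detect_fluorescence(movie$fluor, config$detect), tm)
  write_table_csv(rbind(dets_p, dets_f), file.path(out, "detections.csv"))

  say("tracking %d detections ...", nrow(dets_p))
  tracking <- track_trenches(dets_p, config$track)
  trk_out <- merge(tracking$points,
                   tracking$tracks[, c("track_id", "parent_track_id")],
                   by = "track_id")
  trk_out$t_hours <- (trk_out$frame - 1) * cfg$phase_interval
  write_table_csv(trk_out[order(trk_out$track_id, trk_out$frame), ],
                  file.path(out, "tracks.csv"))

  say("extracting events ...")
  div <- extract_divisions(tracking, cfg$phase_interval)
  deaths <- match_death(tracking, dets_f, cfg$drug_add_time,
                        cfg$phase_interval, cfg$fluor_interval,
                        config$track)
  acct <- accounting(tracking, length(movie$phase),
                     died_track_ids = deaths$phase_track[
                       !is.na(deaths$phase_track)])
  ev_out <- div
  write_table_csv(ev_out, file.path(out, "events.csv"))
  write_table_csv(deaths, file.path(out, "deaths.csv"))

  say("analysing ...")
  analysis <- analyze_events(div, deaths, config, out)

  manifest <- list(
    package = "trenchlapse",
    version = as.character(utils::packageVersion("trenchlapse")),
    seed = config$seed,
    config = unclass_deep(config),
    config_hash = fnv1a(jsonlite::toJSON(unclass_deep(config),
                                         auto_unbox = TRUE, digits = NA)),
    accounting = acct[c("N0", "N_tracked_divided", "N_not_divided",
                        "N_losses")]
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = config, events = events, movie = movie,
                 detections_phase = dets_p, detections_fluor = dets_f,
                 tracking = tracking, divisions = div, deaths = deaths,
                 accounting = acct, analysis = analysis))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Statistical summary of one pipeline run
#'
#' Computes the downstream statistics for a set of extracted divisions and
#' death assignments: log-normal and gamma fits of the cycle durations,
#' the sister-pair correlation with its random-pairing baseline, the mean
#' absolute sister difference, and the time-to-death summary (mean, n and
#' KDE mode). When `out_dir` is given, writes `analysis.json` and
#' diagnostic plots (cycle-duration histogram with fits, TTD density).
#'
#' @param div divisions table from [extract_divisions()].
#' @param deaths deaths table from [match_death()].
#' @param config a [pipeline_config()] (its seed drives pairing/bootstrap).
#' @param out_dir optional output directory.
#' @return a named list of results (see description).
#' @export
analyze_events <- function(div, deaths, config, out_dir = NULL) {
  durs <- c(div$dur1, div$dur2)
  durs <- durs[is.finite(durs) & durs > 0]
  res <- list()
  if (length(durs) >= 5L) {
    res$cycle_lognormal <- unclass(fit_distribution(durs, "lognormal"))
    res$cycle_gamma <- tryCatch(
      unclass(fit_distribution(durs, "gamma")), error = function(e) NULL)
    res$cycle_mean <- mean(durs)
    res$cycle_sd <- stats::sd(durs)
    res$n_durations <- length(durs)
  }
  ok_pairs <- div[is.finite(div$dur1) & is.finite(div$dur2), ]
  if (nrow(ok_pairs) >= 3L) {
    sp <- pair_sisters(data.frame(
      trench_id = rep(ok_pairs$trench_id, 2L),
      value = c(ok_pairs$dur1, ok_pairs$dur2)), seed = config$seed)
    if (nrow(sp) >= 3L) {
      cr <- pearson_with_p(sp$v1, sp$v2, seed = config$seed)
      res$sister_duration_r <- cr$r
      res$sister_duration_r_se <- cr$r_se
      res$sister_abs_diff_mean <- mean(abs(sp$v1 - sp$v2))
      rb <- tryCatch(random_pairing_baseline(
        c(sp$v1, sp$v2), rep(sp$trench_id, 2L), seed = config$seed),
        error = function(e) NULL)
      if (!is.null(rb)) res$random_pairing_r <- rb$r_mean
    }
  }
  ttd <- deaths$time_to_death[!deaths$pre_drug &
                                !is.na(deaths$phase_track)]
  if (length(ttd) >= 2L) {
    kd <- ttd_density(ttd)
    res$ttd_mean <- mean(ttd)
    res$ttd_n <- length(ttd)
    res$ttd_kde_mode <- kd$x[which.max(kd$y)]
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(res, file.path(out_dir, "analysis.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (length(durs) >= 5L) {
      grDevices::pdf(file.path(out_dir, "cycle_durations.pdf"), 6, 4)
      graphics::hist(durs, breaks = 20, freq = FALSE,
                     main = "Cycle durations", xlab = "duration [h]")
      xs <- seq(min(durs), max(durs), length.out = 200)
      ln <- res$cycle_lognormal$parameters
      graphics::lines(xs, stats::dlnorm(xs, ln["meanlog"], ln["sdlog"]),
                      col = "red", lty = 2)
      if (!is.null(res$cycle_gamma)) {
        gp <- res$cycle_gamma$parameters
        graphics::lines(xs, stats::dgamma(xs, gp["shape"], gp["rate"]),
                        col = "blue", lty = 3)
      }
      grDevices::dev.off()
    }
    if (length(ttd) >= 2L) {
      kd <- ttd_density(ttd)
      grDevices::pdf(file.path(out_dir, "ttd_density.pdf"), 6, 4)
      graphics::plot(kd$x, kd$y, type = "l", main = "Time-to-death KDE",
                     xlab = "time-to-death [h]", ylab = "density")
      grDevices::dev.off()
    }
  }
  res
}
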