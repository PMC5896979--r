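#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its documented default. The
#' defaults reproduce the reference configuration: 7 um virtual boundaries,
#' sigma 2.5 px smoothing, a 51 px adaptive-threshold window with an offset
#' of 20% of the dynamic range,
#' watershed h-depth 2 px, 30-600 um^2 area bounds with circularity 0.3,
#' pairing cost weights (2, 2) under a 40 um gate, 20% ratio-jump and
#' 5-point-rise rupture triggers, and a one-frame mitosis window with a 40 um
#' vicinity radius.
#'
#' @param ... overrides of any default (must name existing fields).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.8,
    frame_interval_min = 10,
    migration_direction = "up",
    # registration
    hough_radius_px = c(6, 14),
    hough_sensitivity = 0.5,
    boundary_offset_um = 7,
    # preprocessing
    smooth_sigma = 2.5,
    max_drift_px = 20,
    # segmentation
    threshold_window_px = 51,
    threshold_offset_frac = 0.2,
    h_depth = 2,
    min_area_um2 = 30,
    max_area_um2 = 600,
    min_circularity = 0.3,
    # tracking
    max_distance_um = 40,
    w_intensity = 2,
    w_area = 2,
    # rupture detection
    jump_frac = 0.20,
    rise_len = 5L,
    min_rise_frac = 0.01,
    baseline_tol_frac = 0.10,
    delta_zero_tol = 0.05,
    vicinity_um = 40,
    mitosis_window = 1L,
    # overlay
    trail_window_min = 360
  )
  mods <- list(...)
  unknown <- setdiff(names(mods), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(mods)] <- mods
  structure(cfg, class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param config an [analysis_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$hough_radius_px <- as.numeric(unlist(vals$hough_radius_px))
  do.call(analysis_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: device registration on the first transmitted-light
#' frame (pillar detection, rotation, virtual boundaries), drift estimation
#' and stabilization, per-frame nucleus segmentation, frame-to-frame
#' tracking, constriction-transit detection, rupture detection and mitosis
#' reclassification. Each stage consumes only upstream products; per-stage
#' object counts are collected in the result's `log`.
#'
#' @param sequence an [image_sequence()] (or a path readable by
#'   [read_sequence()]).
#' @param config an [analysis_config()].
#' @param register detect device geometry (set `FALSE` for unconfined 2-D
#'   migration data; transit detection is then skipped).
#' @return a `results_bundle`: list with `geometry`, `drift`,
#'   `observations`, `tracks`, `transits`, `ruptures`, `mitoses`, `config`,
#'   `log`, and the stabilized `sequence`.
#' @export
run_pipeline <- function(sequence, config = analysis_config(),
                         register = TRUE) {
  if (is.character(sequence)) sequence <- read_sequence(sequence)
  stopifnot(inherits(sequence, "image_sequence"))
  log <- list()

  geometry <- NULL
  if (register) {
    reg <- register_device(get_frame(sequence, 1L, "transmitted"),
                           radius_range_px = config$hough_radius_px,
                           sensitivity = config$hough_sensitivity,
                           boundary_offset_um = config$boundary_offset_um,
                           pixel_size_um = config$pixel_size_um)
    geometry <- reg$geometry
    sequence <- rotate_sequence(sequence, reg$rotation_deg)
    log$n_pillars <- nrow(geometry$pillars)
    log$rotation_deg <- reg$rotation_deg
  }

  drift <- estimate_drift(sequence, max_shift = config$max_drift_px)
  sequence <- stabilize(sequence, drift)
  log$max_drift <- max(abs(c(drift$dx, drift$dy)))

  T <- n_frames(sequence)
  # anchor the adaptive-threshold offset to the sequence-wide dynamic range
  # (robust quantiles), so cell-free frames do not dissolve into noise
  nuc_ch <- channel_index(sequence, "nuclear")
  rng <- diff(stats::quantile(sequence$frames[, , nuc_ch, ],
                              c(0.001, 0.999), names = FALSE))
  threshold_offset <- config$threshold_offset_frac * rng
  per_frame <- vector("list", T)
  for (t in seq_len(T)) {
    seg <- segment_frame(get_frame(sequence, t, "nuclear"),
                         get_frame(sequence, t, "reporter"),
                         frame_index = t, geometry = geometry,
                         config = config, threshold_offset = threshold_offset)
    per_frame[[t]] <- seg$observations
  }
  log$n_observations <- sum(vapply(per_frame, nrow, 0L))

  tr <- build_tracks(per_frame,
                     max_distance_um = config$max_distance_um,
                     pixel_size_um = config$pixel_size_um,
                     w_intensity = config$w_intensity,
                     w_area = config$w_area)
  log$n_tracks <- nrow(tr$tracks)

  transits <- if (!is.null(geometry) && nrow(tr$observations) > 0L) {
    detect_all_transits(tr$observations, geometry,
                        sequence$frame_interval_min,
                        config$migration_direction)
  } else {
    detect_transits(data.frame(frame = integer(), track_id = integer()),
                    list(rows = list()), sequence$frame_interval_min)
  }
  log$n_transits <- nrow(transits)

  ruptures <- if (nrow(tr$observations) > 0L) {
    detect_ruptures(tr$observations, sequence$frame_interval_min,
                    jump_frac = config$jump_frac,
                    rise_len = config$rise_len,
                    min_rise_frac = config$min_rise_frac,
                    baseline_tol_frac = config$baseline_tol_frac,
                    delta_zero_tol = config$delta_zero_tol)
  } else {
    detect_ruptures(data.frame(track_id = integer(), frame = integer(),
                               mean_nuclear = numeric(),
                               mean_reporter = numeric()),
                    sequence$frame_interval_min)
  }
  rec <- reclassify_mitosis(tr$observations, tr$tracks, ruptures,
                            vicinity_um = config$vicinity_um,
                            pixel_size_um = config$pixel_size_um,
                            mitosis_window = config$mitosis_window)
  log$n_ruptures <- nrow(rec$ruptures)
  log$n_mitoses <- nrow(rec$mitoses)

  structure(list(geometry = geometry, drift = drift,
                 observations = tr$observations, tracks = rec$tracks,
                 transits = transits, ruptures = rec$ruptures,
                 mitoses = rec$mitoses, config = config, log = log,
                 sequence = sequence),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("results_bundle:\n")
  for (nm in names(x$log)) cat(sprintf("  %s: %s\n", nm,
                                       format(x$log[[nm]], digits = 4)))
  invisible(x)
}

#' Export pipeline results to CSV and JSON
#'
#' Writes `tracks.csv` (per-observation rows), `transits.csv`,
#' `ruptures.csv`, `mitoses.csv`, `drift.csv` and `geometry.json` with fixed
#' column order, so repeated runs on identical input produce byte-identical
#' files.
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
export_results <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, cols, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df[, cols, drop = FALSE], p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  obs <- bundle$observations
  if (nrow(obs) == 0L) {
    obs <- data.frame(track_id = integer(), frame = integer(), x = numeric(),
                      y = numeric(), area_px2 = numeric(),
                      mean_nuclear = numeric(), mean_reporter = numeric(),
                      in_constriction = logical())
  }
  wr(obs, c("track_id", "frame", "x", "y", "area_px2", "mean_nuclear",
            "mean_reporter", "in_constriction"), "tracks.csv")
  wr(bundle$transits, c("track_id", "row_index", "entry_frame", "exit_frame",
                        "outcome", "transit_time_min", "adjacent_to_previous"),
     "transits.csv")
  wr(bundle$ruptures, c("track_id", "start_frame", "end_frame",
                        "duration_min", "trigger", "baseline_ratio"),
     "ruptures.csv")
  wr(bundle$mitoses, c("parent_track_id", "daughter_track_ids",
                       "division_frame"), "mitoses.csv")
  wr(bundle$drift, c("frame", "dx", "dy"), "drift.csv")
  if (!is.null(bundle$geometry)) {
    gp <- file.path(out_dir, "geometry.json")
    write_geometry(bundle$geometry, gp)
    paths <- c(paths, gp)
  }
  invisible(paths)
}
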