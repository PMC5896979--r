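# Shared fixtures. Suite pipeline runs are expensive, so they are computed
# once per session and cached; unit fixtures are built fresh per test.

.suite_cache <- new.env(parent = emptyenv())

suite_result <- function(suite_name, index, frame_interval_min) {
  key <- paste0(suite_name, "_", index)
  if (!exists(key, envir = .suite_cache)) {
    sc <- standard_suites()[[suite_name]][[index]]
    r <- render_scenario(sc)
    b <- run_pipeline(r$sequence,
                      analysis_config(frame_interval_min = frame_interval_min))
    assign(key, list(scenario = sc, rendered = r, bundle = b),
           envir = .suite_cache)
  }
  get(key, envir = .suite_cache)
}

# simple three-row geometry used by event-logic tests (no image involved)
toy_geometry <- function(rows_y = c(80, 190, 300), offset_px = 8.75,
                         x_centers = seq(80, 440, by = 40)) {
  rows <- lapply(rows_y, function(cy) {
    list(centerline_y = cy, upper_boundary_y = cy - offset_px,
         lower_boundary_y = cy + offset_px, x_centers = x_centers)
  })
  structure(list(pillars = data.frame(x = numeric(), y = numeric(),
                                      r = numeric()),
                 rotation_deg = 0, rows = rows, boundary_offset_um = 7,
                 pixel_size_um = 0.8),
            class = "device_geometry")
}

# observation rows for a scripted vertical bbox trajectory (event-logic tests)
obs_from_path <- function(track_id, frames, y_center, half_height = 7,
                          x = 100) {
  data.frame(frame = frames, label = 1L, x = x, y = y_center,
             min_x = x - 9, min_y = y_center - half_height,
             max_x = x + 9, max_y = y_center + half_height,
             area_px2 = 198, mean_nuclear = 0.5, mean_reporter = 0.5,
             in_constriction = FALSE, track_id = track_id)
}

# observation table carrying an explicit ratio trace (rupture tests)
obs_from_ratio <- function(track_id, ratio, reporter = 0.5, x = 50, y = 50) {
  data.frame(frame = seq_along(ratio), label = 1L, x = x, y = y,
             min_x = x - 9, min_y = y - 7, max_x = x + 9, max_y = y + 7,
             area_px2 = 198, mean_nuclear = ratio * reporter,
             mean_reporter = reporter, in_constriction = FALSE,
             track_id = track_id)
}

# binary mask of one or more ellipses on an H x W canvas
ellipse_mask <- function(centers, a, b, H = 80, W = 120) {
  m <- matrix(0, H, W)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  for (i in seq_len(nrow(centers))) {
    inside <- ((xs - centers$x[i]) / a)^2 + ((ys - centers$y[i]) / b)^2 <= 1
    m[inside] <- 1
  }
  m
}
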