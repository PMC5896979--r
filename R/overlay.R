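# Verification overlay rendering: annotated RGB frames for human review.
# Purely presentational; nothing downstream depends on it.

GLYPHS <- list(
  R = c("110", "101", "110", "101", "101"),
  D = c("110", "101", "101", "101", "110")
)

draw_glyph <- function(img, glyph, x, y, value = 1) {
  rows <- GLYPHS[[glyph]]
  for (gy in seq_along(rows)) {
    bits <- strsplit(rows[gy], "")[[1L]]
    for (gx in seq_along(bits)) {
      if (bits[gx] == "1") {
        yy <- y + gy - 1L; xx <- x + gx - 1L
        if (yy >= 1 && yy <= dim(img)[1L] && xx >= 1 && xx <= dim(img)[2L]) {
          img[yy, xx, ] <- value
        }
      }
    }
  }
  img
}

draw_hline <- function(img, y, channel, value = 1) {
  y <- round(y)
  if (y >= 1 && y <= dim(img)[1L]) img[y, , channel] <- value
  img
}

draw_box <- function(img, bb, channel, value = 1) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  ys <- max(1, bb["min_y"]):min(H, bb["max_y"])
  xs <- max(1, bb["min_x"]):min(W, bb["max_x"])
  img[ys[1L], xs, channel] <- value
  img[ys[length(ys)], xs, channel] <- value
  img[ys, xs[1L], channel] <- value
  img[ys, xs[length(xs)], channel] <- value
  img
}

#' Render an annotated verification sequence
#'
#' Produces one RGB frame per input frame: the nuclear-marker channel in red,
#' the reporter in green, constriction boundary lines in blue, centroid
#' trails over the last `trail_window_min` minutes in yellow, and event
#' marks — a box plus letter "R" at rupture starts and "D" at divisions.
#' Written as a multi-page RGB TIFF for inspection in any viewer.
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @param out_path output TIFF path.
#' @param trail_window_min trail history length in minutes.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(bundle, out_path,
                           trail_window_min = bundle$config$trail_window_min) {
  seq <- bundle$sequence
  T <- n_frames(seq)
  H <- dim(seq$frames)[1L]; W <- dim(seq$frames)[2L]
  trail_frames <- max(1L, floor(trail_window_min / seq$frame_interval_min))
  obs <- bundle$observations
  pages <- vector("list", T)
  norm01 <- function(m) {
    r <- range(m); if (diff(r) == 0) m * 0 else (m - r[1L]) / diff(r)
  }
  for (t in seq_len(T)) {
    img <- array(0, dim = c(H, W, 3L))
    img[, , 1L] <- norm01(get_frame(seq, t, "nuclear"))
    img[, , 2L] <- norm01(get_frame(seq, t, "reporter"))
    if (!is.null(bundle$geometry)) {
      for (rw in bundle$geometry$rows) {
        img <- draw_hline(img, rw$upper_boundary_y, 3L)
        img <- draw_hline(img, rw$lower_boundary_y, 3L)
      }
    }
    if (nrow(obs) > 0L) {
      hist <- obs[obs$frame <= t & obs$frame > t - trail_frames, , drop = FALSE]
      px <- round(hist$x); py <- round(hist$y)
      ok <- px >= 1 & px <= W & py >= 1 & py <= H
      img[cbind(py[ok], px[ok], 1L)] <- 1
      img[cbind(py[ok], px[ok], 2L)] <- 1
    }
    for (i in seq_len(nrow(bundle$ruptures))) {
      ev <- bundle$ruptures[i, ]
      if (!is.na(ev$start_frame) && ev$start_frame == t) {
        o <- obs[obs$track_id == ev$track_id & obs$frame == t, , drop = FALSE]
        if (nrow(o) == 1L) {
          img <- draw_box(img, c(min_x = o$min_x, min_y = o$min_y,
                                 max_x = o$max_x, max_y = o$max_y), 1L)
          img <- draw_glyph(img, "R", o$max_x + 2L, o$min_y)
        }
      }
    }
    for (i in seq_len(nrow(bundle$mitoses))) {
      ev <- bundle$mitoses[i, ]
      if (ev$division_frame == t) {
        o <- obs[obs$track_id == ev$parent_track_id & obs$frame == t, ,
                 drop = FALSE]
        if (nrow(o) == 1L) {
          img <- draw_box(img, c(min_x = o$min_x, min_y = o$min_y,
                                 max_x = o$max_x, max_y = o$max_y), 2L)
          img <- draw_glyph(img, "D", o$max_x + 2L, o$min_y)
        }
      }
    }
    pages[[t]] <- pmin(pmax(img, 0), 1)
  }
  tiff::writeTIFF(pages, out_path, bits.per.sample = 8L)
  invisible(out_path)
}
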