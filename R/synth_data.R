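#' Specify a synthetic pillared migration device
#'
#' The emulated device consists of `n_rows` horizontal rows of round pillars;
#' the gap between adjacent pillars is a constriction. The whole pillar grid
#' can be rotated about the image centre to emulate a device mounted at an
#' angle, which is what the registration stage must undo.
#'
#' @param n_rows number of constriction rows.
#' @param pillars_per_row pillars in each row.
#' @param pitch_px centre-to-centre pillar spacing, px.
#' @param radius_px pillar radius, px.
#' @param row_spacing_px vertical distance between row centerlines, px.
#' @param first_row_y y of the top row centerline before rotation, px.
#' @param first_pillar_x x of the leftmost pillar before rotation, px.
#' @param rotation_deg rotation of the grid about the image centre, degrees.
#' @return a `device_spec` list.
#' @export
device_spec <- function(n_rows = 3, pillars_per_row = 11, pitch_px = 40,
                        radius_px = 8, row_spacing_px = 110,
                        first_row_y = 80, first_pillar_x = 60,
                        rotation_deg = 0) {
  structure(as.list(environment()), class = "device_spec")
}

# Pillar centres in image coordinates (grid rotated about the image centre).
pillar_centers <- function(device, width, height) {
  g <- expand.grid(
    x = device$first_pillar_x + (seq_len(device$pillars_per_row) - 1L) *
      device$pitch_px,
    y = device$first_row_y + (seq_len(device$n_rows) - 1L) *
      device$row_spacing_px)
  rotate_points(g$x, g$y, device$rotation_deg, width, height)
}

# Forward rotation of points about the image centre, matching rotate_frame():
# content rotated by +angle maps p -> R(angle) (p - c) + c.
rotate_points <- function(x, y, angle, width, height) {
  th <- angle * pi / 180
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  data.frame(x = cos(th) * (x - cx) - sin(th) * (y - cy) + cx,
             y = sin(th) * (x - cx) + cos(th) * (y - cy) + cy)
}

#' Assemble a synthetic time-lapse scenario
#'
#' A scenario fixes everything about a rendered sequence: the device, the
#' scripted nuclei, stage drift, photobleaching, the noise level and the RNG
#' seed. Identical scenarios render to bit-identical stacks.
#'
#' @param name scenario name.
#' @param frames number of frames T.
#' @param width,height image size in px.
#' @param device a [device_spec()].
#' @param nuclei list of nucleus scripts (see [script_stationary()] and
#'   friends); each is a list with `id` and a per-frame `script` data.frame.
#' @param drift data.frame `(frame, dx, dy)` or `NULL` for no drift.
#' @param bleach per-frame multiplicative factor for both fluorescence
#'   channels (length `frames`), or `NULL` for none.
#' @param noise_sigma per-pixel Gaussian noise s.d. (intensity units).
#' @param pixel_size_um,frame_interval_min calibration.
#' @param truth optional list of scripted ground-truth event tables.
#' @param seed RNG seed for the noise.
#' @return a `scenario` object.
#' @export
scenario <- function(name, frames, width = 520, height = 360,
                     device = device_spec(), nuclei = list(),
                     drift = NULL, bleach = NULL, noise_sigma = 0.02,
                     pixel_size_um = 0.8, frame_interval_min = 10,
                     truth = list(), seed = 1L) {
  if (is.null(drift)) {
    drift <- data.frame(frame = seq_len(frames), dx = 0L, dy = 0L)
  }
  if (is.null(bleach)) bleach <- rep(1, frames)
  stopifnot(nrow(drift) == frames, length(bleach) == frames,
            drift$dx[1L] == 0, drift$dy[1L] == 0)
  structure(as.list(environment()), class = "scenario")
}

# --- nucleus scripting -------------------------------------------------------

new_script <- function(frame, x, y, a = 9, b = 7, shape = "ellipse",
                       sep = 0, bridge_w = 5, nuclear_level = 0.5,
                       reporter_level = 0.5, halo_level = 0) {
  data.frame(frame = frame, x = x, y = y, a = a, b = b, shape = shape,
             sep = sep, bridge_w = bridge_w, nuclear_level = nuclear_level,
             reporter_level = reporter_level, halo_level = halo_level)
}

#' Script a stationary or drifting-path nucleus
#'
#' @param id nucleus identity.
#' @param frames frame indices covered.
#' @param x,y centre path, px (scalars are recycled).
#' @param a,b ellipse semi-axes, px.
#' @param nuclear_level,reporter_level per-frame mean channel intensities
#'   inside the nucleus (scalars recycled).
#' @return a nucleus script (list with `id`, `script`).
#' @export
script_stationary <- function(id, frames, x, y, a = 9, b = 7,
                              nuclear_level = 0.5, reporter_level = 0.5) {
  list(id = id,
       script = new_script(frames, rep_len(x, length(frames)),
                           rep_len(y, length(frames)), a, b,
                           nuclear_level = rep_len(nuclear_level, length(frames)),
                           reporter_level = rep_len(reporter_level, length(frames))))
}

# Effective vertical half-extent of the rendered shape (for truth bboxes).
script_half_height <- function(s) {
  ifelse(s$shape == "dumbbell", s$sep / 2 + s$b * 5 / 7, s$b)
}

#' Script a constriction-transit trajectory
#'
#' Builds a nucleus that approaches a constriction row from below (migration
#' toward decreasing y) and either passes it, fails and retreats, or merely
#' grazes the boundary for a single time point. While the centre is within
#' the boundary band the nucleus is rendered as a dumbbell (two lobes
#' bridged through the pore). The scripted ground-truth transit event is
#' derived analytically from the scripted path and the row geometry.
#'
#' @param id nucleus identity.
#' @param x constriction x (a pore midpoint), px.
#' @param row_y row centerline y, px.
#' @param type `"success"`, `"failure"`, `"graze"`, `"parallel"` or
#'   `"ongoing"`.
#' @param start_frame first frame of the approach.
#' @param total_frames scenario frame count.
#' @param dwell extra frames spent squeezing at the row centre (stretches the
#'   transit time).
#' @param a,b semi-axes of the undeformed nucleus, px.
#' @param nuclear_level,reporter_level channel intensities.
#' @return nucleus script with an additional `path` data.frame used for truth.
#' @export
script_transit <- function(id, x, row_y, type = "success", start_frame = 1L,
                           total_frames = 60L, dwell = 0L, a = 9, b = 7,
                           nuclear_level = 0.5, reporter_level = 0.5) {
  far <- 45; hold <- row_y + far
  ys <- switch(
    type,
    success = c(row_y + c(45, 39, 33, 27, 21, 15, 10, 4),
                rep(row_y - 2, dwell),
                row_y + c(-2, -10, -20, -28, -35)),
    failure = c(row_y + c(45, 39, 33, 27, 21, 14, 9, 7),
                rep(row_y + 7, dwell),
                row_y + c(12, 20, 27, 34)),
    graze = c(rep(row_y + 20, 4), row_y + 11, rep(row_y + 20, 6)),
    parallel = c(rep(row_y + 20, 3), row_y + 11, rep(row_y + 20, 7)),
    ongoing = c(row_y + c(45, 39, 33, 27, 21, 15, 10, 4),
                rep(row_y - 2, max(dwell, 2L))),
    stop("unknown transit type: ", type))
  xs <- if (type == "parallel") x - (seq_along(ys) - 1L) * 6 else rep(x, length(ys))
  frames <- start_frame + seq_along(ys) - 1L
  if (type != "ongoing") {
    # park the nucleus at its final position for the rest of the movie
    extra <- frames[length(frames)] + seq_len(max(0L, total_frames -
                                                    frames[length(frames)]))
    frames <- c(frames, extra)
    ys <- c(ys, rep(ys[length(ys)], length(extra)))
    xs <- c(xs, rep(xs[length(xs)], length(extra)))
  }
  keep <- frames <= total_frames
  frames <- frames[keep]; ys <- ys[keep]; xs <- xs[keep]
  in_band <- abs(ys - row_y) <= 6
  s <- new_script(frames, xs, ys, a, b,
                  shape = ifelse(in_band, "dumbbell", "ellipse"),
                  sep = ifelse(in_band, 14, 0),
                  bridge_w = 5,
                  nuclear_level = nuclear_level,
                  reporter_level = reporter_level)
  list(id = id, script = s)
}

# Independent re-derivation of transit truth from a scripted path: simple
# boundary-crossing walk over analytic bounding boxes (kept separate from the
# detector's state machine on purpose).
truth_transits_for_script <- function(ns, geometry_rows, frame_interval_min) {
  s <- ns$script
  h <- script_half_height(s)
  out <- list()
  for (ri in seq_along(geometry_rows)) {
    rw <- geometry_rows[[ri]]
    top <- s$y - h; bot <- s$y + h
    state <- ifelse(bot < rw$upper_boundary_y, "passed",
                    ifelse(top < rw$lower_boundary_y & bot > rw$upper_boundary_y,
                           "attempting", "outside"))
    entry <- NA_integer_; natt <- 0L
    for (i in seq_along(state)) {
      if (is.na(entry)) {
        if (state[i] == "attempting") { entry <- s$frame[i]; natt <- 1L }
      } else if (state[i] == "attempting") {
        natt <- natt + 1L
      } else {
        if (natt > 1L) {
          out[[length(out) + 1L]] <- data.frame(
            id = ns$id, row_index = ri, entry_frame = entry,
            exit_frame = s$frame[i],
            outcome = if (state[i] == "passed") "success" else "failure",
            transit_time_min = (s$frame[i] - entry) * frame_interval_min)
        }
        entry <- NA_integer_; natt <- 0L
      }
    }
    if (!is.na(entry) && natt > 1L) {
      out[[length(out) + 1L]] <- data.frame(
        id = ns$id, row_index = ri, entry_frame = entry,
        exit_frame = s$frame[length(state)], outcome = "ongoing",
        transit_time_min = NA_real_)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id = integer(), row_index = integer(),
                      entry_frame = integer(), exit_frame = integer(),
                      outcome = character(), transit_time_min = numeric()))
  }
  do.call(rbind, out)
}

#' Script a nuclear envelope rupture trace
#'
#' A stationary nucleus whose reporter level drops at `start_frame` so that
#' the nuclear-marker/reporter ratio jumps by `jump_frac`, then recovers
#' exponentially toward baseline with time constant `tau` frames. The
#' scripted truth start is `start_frame`; the truth end is derived by
#' applying the closure rule (return to within 10% of baseline with settled
#' delta) to the noise-free scripted ratio, so the scripted duration is
#' exactly what an ideal detector should report.
#'
#' @param id nucleus identity.
#' @param frames scenario frame count.
#' @param x,y position.
#' @param start_frame rupture onset frame.
#' @param jump_frac relative ratio jump at onset (e.g. 0.4 = 40%).
#' @param tau recovery time constant, frames.
#' @param level baseline intensity of both channels.
#' @return nucleus script with `rupture` truth attached.
#' @export
script_rupture_trace <- function(id, frames, x, y, start_frame, jump_frac,
                                 tau = 3, level = 0.5) {
  t <- seq_len(frames)
  q <- rep(1, frames)  # scripted ratio relative to baseline
  post <- t >= start_frame
  q[post] <- 1 + jump_frac * exp(-(t[post] - start_frame) / tau)
  reporter <- level / q
  halo <- 0.3 * (level - reporter)  # escaped reporter around the nucleus
  s <- new_script(t, rep(x, frames), rep(y, frames),
                  nuclear_level = level, reporter_level = reporter,
                  halo_level = halo)
  end <- truth_rupture_end(q, start_frame)
  list(id = id, script = s,
       rupture = data.frame(id = id, start_frame = start_frame,
                            end_frame = end, jump_frac = jump_frac,
                            expected_detected = jump_frac > 0.20))
}

# Closure rule applied to the scripted relative ratio (baseline 1).
truth_rupture_end <- function(q, start_frame, baseline_tol = 0.10,
                              delta_tol = 0.05) {
  departed <- FALSE
  for (i in start_frame:length(q)) {
    if (q[i] > 1 + baseline_tol) {
      departed <- TRUE
    } else if (departed && i > start_frame &&
               abs(q[i] - q[i - 1L]) <= delta_tol) {
      return(i)
    }
  }
  NA_integer_
}

#' Script a cell division
#'
#' The parent nucleus shows a rupture-like ratio jump at `division_frame`
#' (nuclear envelope breakdown) and from the next frame on is replaced by two
#' daughter nuclei of roughly half the area, one near the parent position and
#' one displaced by `sep_px`. The pipeline should reclassify the apparent
#' rupture as mitosis because a new track appears in the parent's vicinity.
#'
#' @param id parent identity (daughter gets `id + daughter_id_offset`).
#' @param frames scenario frame count.
#' @param x,y parent position.
#' @param division_frame frame of nuclear envelope breakdown.
#' @param sep_px displacement of the second daughter, px.
#' @param level baseline channel intensity.
#' @param daughter_id_offset added to `id` for the new daughter's identity.
#' @return list of two nucleus scripts plus `division` truth.
#' @export
script_division <- function(id, frames, x, y, division_frame, sep_px = 26,
                            level = 0.5, daughter_id_offset = 1000L) {
  t_parent <- seq_len(frames)
  rep_lvl <- rep(level, frames)
  rep_lvl[t_parent == division_frame] <- level / 2  # ratio doubles at NEBD
  a <- rep(9, frames); b <- rep(7, frames)
  after <- t_parent > division_frame
  a[after] <- 6.5; b[after] <- 5.5
  ypar <- rep(y, frames); ypar[after] <- y - sep_px / 2
  parent <- list(id = id,
                 script = new_script(t_parent, rep(x, frames), ypar, a, b,
                                     nuclear_level = level,
                                     reporter_level = rep_lvl))
  t_d <- (division_frame + 1L):frames
  daughter <- list(id = id + daughter_id_offset,
                   script = new_script(t_d, rep(x, length(t_d)),
                                       rep(y + sep_px / 2, length(t_d)),
                                       a = 6.5, b = 5.5,
                                       nuclear_level = level,
                                       reporter_level = level))
  list(parent = parent, daughter = daughter,
       division = data.frame(parent_id = id,
                             daughter_id = id + daughter_id_offset,
                             division_frame = division_frame))
}

# --- rendering ---------------------------------------------------------------

add_soft_ellipse <- function(img, cx, cy, a, b, level) {
  H <- nrow(img); W <- ncol(img)
  if (cx + a + 2 < 1 || cx - a - 2 > W ||
      cy + b + 2 < 1 || cy - b - 2 > H) {
    return(img)   # fully outside the frame (e.g. a clipped pillar row)
  }
  xs <- max(1L, floor(cx - a - 2)):min(W, ceiling(cx + a + 2))
  ys <- max(1L, floor(cy - b - 2)):min(H, ceiling(cy + b + 2))
  rho <- sqrt(outer(((ys - cy) / b)^2, ((xs - cx) / a)^2, "+"))
  cov <- pmin(pmax((1 - rho) * min(a, b) + 0.5, 0), 1)
  img[ys, xs] <- img[ys, xs] + level * cov
  img
}

# union coverage of two lobes plus a connecting bridge
add_dumbbell <- function(img, cx, cy, a, b, sep, bridge_w, level) {
  H <- nrow(img); W <- ncol(img)
  lb <- b * 5 / 7; la <- a * 7 / 9  # lobes slightly smaller than free shape
  ylo <- cy - sep / 2; yhi <- cy + sep / 2
  xs <- max(1L, floor(cx - a - 2)):min(W, ceiling(cx + a + 2))
  ys <- max(1L, floor(ylo - lb - 2)):min(H, ceiling(yhi + lb + 2))
  if (length(xs) == 0L || length(ys) == 0L) return(img)
  cov_l <- function(y0) {
    rho <- sqrt(outer(((ys - y0) / lb)^2, ((xs - cx) / la)^2, "+"))
    pmin(pmax((1 - rho) * min(la, lb) + 0.5, 0), 1)
  }
  dxm <- abs(outer(rep(1, length(ys)), xs - cx))
  dy_in <- outer(ys, rep(1, length(xs))) >= ylo & outer(ys, rep(1, length(xs))) <= yhi
  cov_b <- pmin(pmax(bridge_w / 2 - dxm + 0.5, 0), 1) * dy_in
  cov <- pmax(pmax(cov_l(ylo), cov_l(yhi)), cov_b)
  img[ys, xs] <- img[ys, xs] + level * cov
  img
}

add_soft_disk <- function(img, cx, cy, r, level) {
  add_soft_ellipse(img, cx, cy, r, r, level)
}

#' Render a scenario into an image sequence plus ground truth
#'
#' The transmitted channel shows dark pillars on a bright background; the
#' nuclear channel shows the scripted ellipses / dumbbells; the reporter
#' channel shows the scripted reporter level inside each nucleus plus a
#' diffuse cytoplasmic halo while reporter signal is scripted as escaped.
#' Stage drift shifts all channels together, photobleaching scales the
#' fluorescence channels, and i.i.d. Gaussian noise is added last. Rendering
#' is deterministic for a fixed scenario (seeded noise).
#'
#' @param sc a [scenario()].
#' @return list with `sequence` (an [image_sequence()]) and `truth` (list:
#'   `tracks`, `pillars`, `drift`, `rotation_deg`, plus any scripted event
#'   tables carried in `sc$truth`).
#' @export
render_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  set.seed(sc$seed)
  H <- sc$height; W <- sc$width; T <- sc$frames
  pil <- pillar_centers(sc$device, W, H)
  frames <- array(0, dim = c(H, W, 3L, T))
  truth_rows <- list()
  for (n in sc$nuclei) {
    s <- n$script
    p <- rotate_points(s$x, s$y, sc$device$rotation_deg, W, H)
    if (any(p$x - s$a < 1 | p$x + s$a > W |
            p$y - script_half_height(s) < 1 |
            p$y + script_half_height(s) > H)) {
      stop(sprintf("nucleus %d scripted outside the frame", n$id))
    }
  }
  for (t in seq_len(T)) {
    dx <- sc$drift$dx[t]; dy <- sc$drift$dy[t]
    tra <- matrix(0.8, H, W)
    for (i in seq_len(nrow(pil))) {
      tra <- add_soft_disk(tra, pil$x[i] + dx, pil$y[i] + dy,
                           sc$device$radius_px, -0.5)
    }
    nuc <- matrix(0.005, H, W)
    rep_ch <- matrix(0.005, H, W)
    for (n in sc$nuclei) {
      s <- n$script[n$script$frame == t, , drop = FALSE]
      if (nrow(s) == 0L) next
      p <- rotate_points(s$x, s$y, sc$device$rotation_deg, W, H)
      cx <- p$x + dx; cy <- p$y + dy
      if (s$shape == "dumbbell") {
        nuc <- add_dumbbell(nuc, cx, cy, s$a, s$b, s$sep, s$bridge_w,
                            s$nuclear_level)
        rep_ch <- add_dumbbell(rep_ch, cx, cy, s$a, s$b, s$sep, s$bridge_w,
                               s$reporter_level)
      } else {
        nuc <- add_soft_ellipse(nuc, cx, cy, s$a, s$b, s$nuclear_level)
        rep_ch <- add_soft_ellipse(rep_ch, cx, cy, s$a, s$b, s$reporter_level)
      }
      if (s$halo_level > 0) {
        # escaped reporter around the nucleus; kept clear of the segmentation
        # mask (which extends a few px beyond the ellipse) so the *nuclear*
        # mean reflects the scripted reporter level
        rh <- 2 * max(s$a, s$b)
        halo <- matrix(0, H, W)
        halo <- add_soft_disk(halo, cx, cy, rh, s$halo_level)
        inner <- matrix(0, H, W)
        inner <- add_soft_ellipse(inner, cx, cy, s$a + 8, s$b + 8, 1)
        rep_ch <- rep_ch + halo * (1 - pmin(inner, 1))
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        id = n$id, frame = t, x = p$x, y = p$y, a = s$a,
        half_height = script_half_height(s),
        nuclear_level = s$nuclear_level, reporter_level = s$reporter_level)
    }
    bl <- sc$bleach[t]
    nuc <- nuc * bl
    rep_ch <- rep_ch * bl
    if (sc$noise_sigma > 0) {
      tra <- tra + matrix(stats::rnorm(H * W, 0, sc$noise_sigma), H, W)
      nuc <- nuc + matrix(stats::rnorm(H * W, 0, sc$noise_sigma), H, W)
      rep_ch <- rep_ch + matrix(stats::rnorm(H * W, 0, sc$noise_sigma), H, W)
    }
    # cameras clip at zero and full well; keeps stacks storable as [0,1] float
    frames[, , 1L, t] <- pmin(pmax(tra, 0), 1)
    frames[, , 2L, t] <- pmin(pmax(nuc, 0), 1)
    frames[, , 3L, t] <- pmin(pmax(rep_ch, 0), 1)
  }
  tracks <- if (length(truth_rows) > 0L) do.call(rbind, truth_rows) else
    data.frame(id = integer(), frame = integer(), x = numeric(),
               y = numeric(), a = numeric(), half_height = numeric(),
               nuclear_level = numeric(), reporter_level = numeric())
  truth <- c(list(tracks = tracks, pillars = pil,
                  pillars_unrotated = pillar_centers(
                    within_device(sc$device, rotation_deg = 0), W, H),
                  drift = sc$drift, rotation_deg = sc$device$rotation_deg),
             sc$truth)
  seq <- image_sequence(frames, sc$pixel_size_um, sc$frame_interval_min)
  list(sequence = seq, truth = truth)
}

within_device <- function(device, ...) {
  mods <- list(...)
  device[names(mods)] <- mods
  device
}

# --- fixed suites ------------------------------------------------------------

#' Fixed named scenario suites
#'
#' Returns the deterministic scenario sets used by the package's validation
#' and acceptance tests:
#' * `registration_suite` — pillar grids at rotations -5 to +5 degrees with
#'   12-24 pillars, no cells;
#' * `tracking_suite` — a standard scene of 12 migrating nuclei (including a
#'   touching pair) over 50 frames with integer sawtooth drift and mild
#'   photobleaching;
#' * `transit_suite` — 20 scripted constriction trajectories (successes with
#'   varying dwell, failures, one-frame grazes and a parallel-motion graze)
#'   split over two scenarios;
#' * `rupture_suite` — 30 scripted rupture traces with ratio jumps of
#'   10-60% and varying recovery speeds, 10 cell divisions and 10 flat
#'   controls, split over five scenarios.
#'
#' All seeds are fixed, so the suites are identical across calls and runs.
#'
#' @return named list of lists of [scenario()] objects.
#' @export
standard_suites <- function() {
  list(registration_suite = registration_suite(),
       tracking_suite = tracking_suite(),
       transit_suite = transit_suite(),
       rupture_suite = rupture_suite())
}

registration_suite <- function() {
  rots <- c(-5, -2.5, 0, 2.5, 5)
  ppr <- c(4L, 6L, 8L, 7L, 5L)
  lapply(seq_along(rots), function(i) {
    scenario(name = sprintf("registration_%02d", i), frames = 1L,
             width = 420, height = 330,
             device = device_spec(pillars_per_row = ppr[i],
                                  pitch_px = 42, radius_px = 8,
                                  row_spacing_px = 100, first_row_y = 65,
                                  first_pillar_x = round((420 - (ppr[i] - 1) * 42) / 2),
                                  rotation_deg = rots[i]),
             noise_sigma = 0.01, frame_interval_min = 10, seed = 100L + i)
  })
}

tracking_suite <- function() {
  T <- 50L
  lanes <- data.frame(
    x0 = c(80, 150, 220, 290, 360, 430, 80, 150, 220, 290, 380, 401),
    y0 = c(130, 150, 132, 148, 135, 152, 250, 262, 248, 260, 252, 252),
    amp = c(10, 14, 8, 12, 9, 13, 11, 8, 12, 10, 6, 6),
    phase = seq(0, 2 * pi, length.out = 12),
    lvl = seq(0.40, 0.62, length.out = 12))
  lanes$phase[12L] <- lanes$phase[11L]  # touching pair moves rigidly
  nuclei <- lapply(seq_len(nrow(lanes)), function(i) {
    t <- seq_len(T)
    x <- lanes$x0[i] + lanes$amp[i] * sin(2 * pi * t / 30 + lanes$phase[i])
    y <- lanes$y0[i] + 0.6 * lanes$amp[i] * cos(2 * pi * t / 24 + lanes$phase[i])
    list(id = i, script = new_script(t, x, y, a = 9, b = 7,
                                     nuclear_level = lanes$lvl[i],
                                     reporter_level = 0.5))
  })
  # nuclei 11 and 12 form a permanently touching pair (21 px = 1.5 minor axes)
  drift <- data.frame(frame = seq_len(T),
                      dx = as.integer(round(4 * sin(2 * pi * seq_len(T) / 16))),
                      dy = as.integer(((seq_len(T) - 1L) %% 8L) - 3L))
  drift$dx[1L] <- 0L; drift$dy[1L] <- 0L
  list(scenario(name = "tracking_standard", frames = T, width = 520,
                height = 380,
                device = device_spec(first_row_y = 70, row_spacing_px = 120),
                nuclei = nuclei, drift = drift,
                bleach = 0.997^(seq_len(T) - 1L), noise_sigma = 0.02,
                frame_interval_min = 10, seed = 201L))
}

transit_suite <- function() {
  T <- 60L
  make_one <- function(idx, seed) {
    dev <- device_spec(pillars_per_row = 11, pitch_px = 44, radius_px = 8,
                       row_spacing_px = 120, first_row_y = 60,
                       first_pillar_x = 40)
    pores <- dev$first_pillar_x + dev$pitch_px * (seq_len(10) - 0.5)
    row_y <- dev$first_row_y + dev$row_spacing_px  # middle row
    types <- c("success", "success", "success", "failure", "graze",
               "success", "failure", "success", "parallel", "ongoing")
    dwell <- c(0, 2, 5, 0, 0, 8, 3, 1, 0, 30)
    start <- c(2, 6, 10, 4, 12, 14, 18, 22, 26, 28) + (idx - 1L)
    nuclei <- lapply(seq_along(types), function(i) {
      script_transit(id = i, x = pores[i], row_y = row_y, type = types[i],
                     start_frame = start[i], total_frames = T,
                     dwell = dwell[i],
                     nuclear_level = 0.42 + 0.02 * i)
    })
    sc <- scenario(name = sprintf("transit_%02d", idx), frames = T,
                   width = 520, height = 360, device = dev, nuclei = nuclei,
                   noise_sigma = 0.015, frame_interval_min = 10, seed = seed)
    off_px <- 7 / sc$pixel_size_um
    rows <- lapply(seq_len(dev$n_rows), function(ri) {
      cy <- dev$first_row_y + (ri - 1L) * dev$row_spacing_px
      list(centerline_y = cy, upper_boundary_y = cy - off_px,
           lower_boundary_y = cy + off_px)
    })
    tt <- do.call(rbind, lapply(nuclei, truth_transits_for_script,
                                geometry_rows = rows,
                                frame_interval_min = sc$frame_interval_min))
    sc$truth <- list(transits = tt)
    sc
  }
  list(make_one(1L, 301L), make_one(2L, 302L))
}

rupture_suite <- function() {
  T <- 40L
  grid_xy <- function() {
    expand.grid(x = seq(70, 470, length.out = 5), y = c(135, 255))
  }
  jump_sets <- list(c(0.10, 0.15, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50, 0.55, 0.60),
                    c(0.12, 0.18, 0.24, 0.28, 0.34, 0.38, 0.44, 0.48, 0.54, 0.58),
                    c(0.10, 0.14, 0.26, 0.32, 0.36, 0.42, 0.46, 0.52, 0.56, 0.60))
  taus <- c(1.5, 2, 3, 4, 5, 6, 2.5, 3.5, 10, 5.5)
  starts <- c(6, 8, 10, 12, 14, 9, 11, 13, 6, 7)
  rupture_scen <- lapply(1:3, function(k) {
    g <- grid_xy()
    scripts <- lapply(seq_len(10), function(i) {
      script_rupture_trace(id = i, frames = T, x = g$x[i], y = g$y[i],
                           start_frame = starts[i],
                           jump_frac = jump_sets[[k]][i], tau = taus[i])
    })
    sc <- scenario(name = sprintf("rupture_%02d", k), frames = T,
                   width = 520, height = 360,
                   nuclei = lapply(scripts, function(s) s[c("id", "script")]),
                   noise_sigma = 0.01, frame_interval_min = 2,
                   seed = 400L + k)
    sc$truth <- list(ruptures = do.call(rbind, lapply(scripts, `[[`, "rupture")))
    sc
  })
  g <- grid_xy()
  div_parts <- lapply(seq_len(10), function(i) {
    script_division(id = i, frames = T, x = g$x[i], y = g$y[i],
                    division_frame = 7L + 2L * i)
  })
  div_nuclei <- unlist(lapply(div_parts, function(p) list(p$parent, p$daughter)),
                       recursive = FALSE)
  div_sc <- scenario(name = "rupture_divisions", frames = T, width = 520,
                     height = 360, nuclei = div_nuclei, noise_sigma = 0.01,
                     frame_interval_min = 2, seed = 404L)
  div_sc$truth <- list(divisions = do.call(rbind,
                                           lapply(div_parts, `[[`, "division")))
  flat_sc <- scenario(name = "rupture_flat", frames = T, width = 520,
                      height = 360,
                      nuclei = lapply(seq_len(10), function(i) {
                        script_stationary(i, seq_len(T), g$x[i], g$y[i],
                                          nuclear_level = 0.45 + 0.01 * i)
                      }),
                      noise_sigma = 0.01, frame_interval_min = 2, seed = 405L)
  flat_sc$truth <- list(flat = TRUE)
  c(rupture_scen, list(div_sc, flat_sc))
}
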