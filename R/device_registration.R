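#' Detect device pillars with a circular Hough transform
#'
#' The microfluidic migration device consists of rows of round PDMS pillars;
#' the gaps between adjacent pillars form the constrictions. Pillars appear as
#' dark discs in the transmitted-light channel. This function finds them with
#' an accumulator-based circular Hough transform: edge pixels (high intensity
#' gradient) vote for candidate centres at every radius in `radius_range_px`,
#' and accumulator peaks above `sensitivity` times the theoretical maximum
#' vote count are reported as circles. Duplicate detections of the same pillar
#' at neighbouring radii are suppressed, keeping the stronger peak.
#'
#' @param transmitted_frame numeric matrix, single transmitted-light frame.
#' @param radius_range_px integer vector `c(min, max)` of candidate radii in
#'   pixels. Default 6-14 px suits the bundled synthetic device; real devices
#'   should set this from the known pillar size and pixel calibration.
#' @param sensitivity fraction (0-1) of the ideal accumulator peak (a full,
#'   sharp circle of matching radius) a peak must reach. Lower values detect fainter or partial circles
#'   at the cost of false positives.
#' @return data.frame with columns `x`, `y` (centre, px), `r` (radius, px) and
#'   `score` (normalised accumulator value), sorted by `(y, x)`.
#' @export
detect_pillars <- function(transmitted_frame, radius_range_px = c(6, 14),
                           sensitivity = 0.5) {
  stopifnot(is.matrix(transmitted_frame),
            length(radius_range_px) == 2L,
            radius_range_px[1L] <= radius_range_px[2L],
            radius_range_px[1L] >= 2)
  H <- nrow(transmitted_frame); W <- ncol(transmitted_frame)

  sm <- EBImage::gblur(transmitted_frame, sigma = 1)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (sm[, 3:W] - sm[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (sm[3:H, ] - sm[1:(H - 2), ]) / 2
  gmag <- sqrt(gx^2 + gy^2)
  gthr <- 0.3 * max(gmag)
  if (gthr <= 0) registration_failure(radius_range_px)
  edge <- which(gmag > gthr)
  if (length(edge) == 0L) registration_failure(radius_range_px)
  ey <- (edge - 1L) %% H + 1L
  ex <- (edge - 1L) %/% H + 1L

  radii <- seq(floor(radius_range_px[1L]), ceiling(radius_range_px[2L]))
  cand <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    ntheta <- max(24L, ceiling(2 * pi * r))
    theta <- 2 * pi * seq_len(ntheta) / ntheta
    # votes toward the centre from each edge pixel at every angle
    cx <- round(rep(ex, each = ntheta) - r * cos(theta))
    cy <- round(rep(ey, each = ntheta) - r * sin(theta))
    ok <- cx >= 1L & cx <= W & cy >= 1L & cy <= H
    acc <- matrix(tabulate(cy[ok] + (cx[ok] - 1L) * H, nbins = H * W), H, W)
    # spread votes so near-integer centres accumulate in one bin
    accs <- box_mean3(acc) * 9
    peaks <- local_maxima(accs, accs >= sensitivity * 9 * ntheta)
    if (nrow(peaks) > 0L) {
      cand[[i]] <- data.frame(x = peaks$x, y = peaks$y, r = r,
                              score = peaks$value / (9 * ntheta))
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) < 2L) registration_failure(radius_range_px)

  # non-maximum suppression across radii and positions
  cand <- cand[order(-cand$score), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    d <- sqrt((kept$x - cand$x[i])^2 + (kept$y - cand$y[i])^2)
    if (all(d >= pmax(kept$r, cand$r[i]))) keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  if (nrow(out) < 2L) registration_failure(radius_range_px)
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

registration_failure <- function(radius_range_px) {
  stop(sprintf(
    "registration failure: fewer than 2 circles detected for radii %g-%g px",
    radius_range_px[1L], radius_range_px[2L]), call. = FALSE)
}

box_mean3 <- function(m) {
  k <- matrix(1 / 9, 3, 3)
  as.matrix(EBImage::filter2(m, k, boundary = 0))
}

local_maxima <- function(m, mask) {
  H <- nrow(m); W <- ncol(m)
  idx <- which(mask)
  if (length(idx) == 0L) return(data.frame(x = numeric(), y = numeric(),
                                           value = numeric()))
  y <- (idx - 1L) %% H + 1L
  x <- (idx - 1L) %/% H + 1L
  inner <- y > 1L & y < H & x > 1L & x < W
  idx <- idx[inner]; y <- y[inner]; x <- x[inner]
  is_max <- rep(TRUE, length(idx))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    is_max <- is_max & m[idx] >= m[idx + dy + dx * H]
  }
  data.frame(x = x[is_max], y = y[is_max], value = m[idx[is_max]])
}

#' Estimate the rotation that makes pillar rows horizontal
#'
#' Pillar centres are clustered into rows (a jump in sorted y larger than one
#' pillar diameter starts a new row), a straight line is fitted through each
#' row with two or more pillars, and the fitted slopes are averaged weighted
#' by row size. The returned angle is the correcting rotation: applying it via
#' [rotate_sequence()] aligns the rows with the image x-axis. A row sloping
#' downward in image coordinates (y increasing with x) yields a negative
#' correcting angle.
#'
#' @param pillars data.frame with columns `x`, `y`, `r` as returned by
#'   [detect_pillars()].
#' @return rotation angle in degrees, in (-45, 45].
#' @export
estimate_rotation <- function(pillars) {
  stopifnot(nrow(pillars) >= 2L)
  if (max(pillars$x) - min(pillars$x) == 0 &&
      max(pillars$y) - min(pillars$y) == 0) {
    stop("degenerate pillar configuration: all centres coincide", call. = FALSE)
  }
  rows <- cluster_pillar_rows(pillars)
  angles <- numeric(0); weights <- numeric(0)
  for (rw in rows) {
    if (nrow(rw) < 2L) next
    if (max(rw$x) - min(rw$x) == 0) next
    slope <- stats::coef(stats::lm(y ~ x, data = rw))[2L]
    angles <- c(angles, atan(slope))
    weights <- c(weights, nrow(rw))
  }
  if (length(angles) == 0L) {
    # single column of pillars or one pillar per row: fall back to the line
    # through all centres (two-pillar case of the docs)
    slope <- stats::coef(stats::lm(y ~ x, data = pillars))[2L]
    angles <- atan(slope); weights <- 1
  }
  ang <- -sum(angles * weights) / sum(weights) * 180 / pi
  if (ang <= -45) ang <- ang + 90
  if (ang > 45) ang <- ang - 90
  ang
}

# Split pillar centres into rows: sort by y, start a new row where the gap
# between consecutive centres exceeds 2x the median radius.
cluster_pillar_rows <- function(pillars) {
  p <- pillars[order(pillars$y, pillars$x), , drop = FALSE]
  gap <- 2 * stats::median(p$r)
  brk <- c(0L, which(diff(p$y) > gap), nrow(p))
  lapply(seq_len(length(brk) - 1L), function(i) {
    p[(brk[i] + 1L):brk[i + 1L], , drop = FALSE]
  })
}

#' Rotate every frame and channel of a sequence
#'
#' Rotates all images by the same angle about the image centre with bilinear
#' interpolation, so that the constriction rows become horizontal before
#' geometry is built. Regions rotated in from outside the frame are filled
#' with the per-channel median intensity of the frame (a robust background
#' estimate). Output dimensions equal input dimensions.
#'
#' @param sequence an [image_sequence()].
#' @param angle rotation in degrees, as returned by [estimate_rotation()].
#' @return rotated `image_sequence`.
#' @export
rotate_sequence <- function(sequence, angle) {
  stopifnot(inherits(sequence, "image_sequence"), is.finite(angle))
  if (angle == 0) return(sequence)
  fr <- sequence$frames
  for (t in seq_len(dim(fr)[4L])) {
    for (c in seq_len(dim(fr)[3L])) {
      m <- fr[, , c, t]
      fr[, , c, t] <- rotate_frame(m, angle, fill = stats::median(m))
    }
  }
  sequence$frames <- fr
  sequence
}

# Bilinear rotation of a matrix about its centre. Positive angle rotates a
# point (x, y) by the matrix [[cos, -sin], [sin, cos]] in image coordinates
# (y down); resampling uses the inverse map.
rotate_frame <- function(m, angle, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  th <- -angle * pi / 180  # inverse mapping
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xo <- rep(seq_len(W), each = H) - cx
  yo <- rep(seq_len(H), times = W) - cy
  xs <- cos(th) * xo - sin(th) * yo + cx
  ys <- sin(th) * xo + cos(th) * yo + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- rep(fill, H * W)
  ok <- x0 >= 1 & x0 + 1 <= W & y0 >= 1 & y0 + 1 <= H
  i00 <- y0[ok] + (x0[ok] - 1) * H
  v <- (1 - fx[ok]) * (1 - fy[ok]) * m[i00] +
       fx[ok] * (1 - fy[ok]) * m[i00 + H] +
       (1 - fx[ok]) * fy[ok] * m[i00 + 1] +
       fx[ok] * fy[ok] * m[i00 + H + 1]
  out[ok] <- v
  matrix(out, H, W)
}

#' Build device geometry from rotated pillar centres
#'
#' Groups pillars (already in rotated coordinates) into rows and derives, for
#' each row, the constriction centerline (mean pillar centre y), the virtual
#' entry and exit boundaries at `centerline +/- boundary_offset_um`, and the
#' x-midpoints between adjacent pillars, which mark the constrictions
#' themselves. The 7 um default boundary offset is the calibration at which
#' automated transit times best matched a panel of expert manual analysts.
#'
#' @param pillars data.frame of pillar circles in rotated coordinates.
#' @param boundary_offset_um distance of each virtual boundary from the row
#'   centerline, micrometres. Must be positive.
#' @param pixel_size_um pixel calibration, micrometres per pixel.
#' @param rotation_deg rotation (degrees) that was applied to reach these
#'   coordinates; stored for provenance.
#' @return an object of class `device_geometry`: list with `pillars`,
#'   `rotation_deg`, `rows` (each with `centerline_y`, `upper_boundary_y`,
#'   `lower_boundary_y`, `x_centers`), `boundary_offset_um`, `pixel_size_um`.
#' @export
build_geometry <- function(pillars, boundary_offset_um = 7,
                           pixel_size_um = 0.8, rotation_deg = 0) {
  stopifnot(boundary_offset_um > 0, pixel_size_um > 0, nrow(pillars) >= 2L)
  off_px <- boundary_offset_um / pixel_size_um
  rows <- cluster_pillar_rows(pillars)
  geom_rows <- lapply(rows, function(rw) {
    cy <- mean(rw$y)
    xs <- sort(rw$x)
    xc <- if (length(xs) >= 2L) (xs[-1L] + xs[-length(xs)]) / 2 else numeric(0)
    list(centerline_y = cy,
         upper_boundary_y = cy - off_px,
         lower_boundary_y = cy + off_px,
         x_centers = xc)
  })
  geom_rows <- geom_rows[order(vapply(geom_rows, `[[`, 0, "centerline_y"))]
  if (length(geom_rows) != 3L) {
    warning(sprintf("expected 3 constriction rows, found %d; proceeding",
                    length(geom_rows)), call. = FALSE)
  }
  structure(
    list(pillars = pillars, rotation_deg = rotation_deg, rows = geom_rows,
         boundary_offset_um = boundary_offset_um,
         pixel_size_um = pixel_size_um),
    class = "device_geometry"
  )
}

#' @export
print.device_geometry <- function(x, ...) {
  cat(sprintf("device_geometry: %d pillars, %d rows, rotation %.3f deg\n",
              nrow(x$pillars), length(x$rows), x$rotation_deg))
  for (i in seq_along(x$rows)) {
    r <- x$rows[[i]]
    cat(sprintf("  row %d: centerline y = %.1f, boundaries [%.1f, %.1f], %d constrictions\n",
                i, r$centerline_y, r$upper_boundary_y, r$lower_boundary_y,
                length(r$x_centers)))
  }
  invisible(x)
}

#' Register the device in a transmitted-light frame
#'
#' Convenience wrapper: detect pillars, estimate the correcting rotation,
#' re-detect pillars on the rotated frame and build the geometry.
#'
#' @inheritParams detect_pillars
#' @inheritParams build_geometry
#' @return list with `geometry` (a `device_geometry`) and `rotation_deg`.
#' @export
register_device <- function(transmitted_frame, radius_range_px = c(6, 14),
                            sensitivity = 0.5, boundary_offset_um = 7,
                            pixel_size_um = 0.8) {
  pil <- detect_pillars(transmitted_frame, radius_range_px, sensitivity)
  ang <- estimate_rotation(pil)
  rot <- rotate_frame(transmitted_frame, ang,
                      fill = stats::median(transmitted_frame))
  pil2 <- detect_pillars(rot, radius_range_px, sensitivity)
  geom <- build_geometry(pil2, boundary_offset_um, pixel_size_um,
                         rotation_deg = ang)
  list(geometry = geom, rotation_deg = ang)
}

#' Write / read device geometry as a JSON sidecar
#'
#' @param geometry a `device_geometry`.
#' @param path file path for the JSON sidecar.
#' @return `write_geometry` returns `path` invisibly; `read_geometry` returns
#'   the reconstructed `device_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  obj <- list(
    pillars = geometry$pillars,
    rotation_deg = geometry$rotation_deg,
    boundary_offset_um = geometry$boundary_offset_um,
    pixel_size_um = geometry$pixel_size_um,
    rows = lapply(geometry$rows, function(r) {
      list(centerline_y = r$centerline_y,
           upper_boundary_y = r$upper_boundary_y,
           lower_boundary_y = r$lower_boundary_y,
           x_centers = as.numeric(r$x_centers))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  rows <- obj$rows
  if (is.data.frame(rows)) {
    rows <- lapply(seq_len(nrow(rows)), function(i) {
      list(centerline_y = rows$centerline_y[i],
           upper_boundary_y = rows$upper_boundary_y[i],
           lower_boundary_y = rows$lower_boundary_y[i],
           x_centers = as.numeric(rows$x_centers[[i]]))
    })
  } else {
    rows <- lapply(rows, function(r) {
      r$x_centers <- as.numeric(unlist(r$x_centers)); r
    })
  }
  structure(
    list(pillars = as.data.frame(obj$pillars),
         rotation_deg = obj$rotation_deg, rows = rows,
         boundary_offset_um = obj$boundary_offset_um,
         pixel_size_um = obj$pixel_size_um),
    class = "device_geometry"
  )
}
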