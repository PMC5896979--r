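#' Binarize a smoothed nuclear-marker frame with a locally adaptive threshold
#'
#' Foreground is every pixel brighter than the mean of its surrounding
#' `window_px` x `window_px` box plus an offset. Local thresholding keeps
#' segmentation robust to the uneven illumination typical of transmitted /
#' widefield microscopy. Holes inside objects (chromatin texture) are filled;
#' objects touching the image border are retained.
#'
#' @param smoothed_nuclear_frame numeric matrix, output of
#'   [smooth_fluorescence()] on the nuclear-marker channel.
#' @param window_px side of the local averaging window (odd), px.
#' @param offset_frac offset above the local mean required to call foreground,
#'   as a fraction of the frame's dynamic range.
#' @param offset absolute offset overriding `offset_frac`. When segmenting a
#'   time-lapse, the offset should be derived once from the whole sequence's
#'   dynamic range (as [run_pipeline()] does): a frame that happens to
#'   contain no cell has a noise-only dynamic range, and a per-frame
#'   fraction of it would dissolve into noise speckles.
#' @return binary matrix (0 background / 1 foreground).
#' @export
binarize_nuclei <- function(smoothed_nuclear_frame, window_px = 51,
                            offset_frac = 0.2, offset = NULL) {
  stopifnot(is.matrix(smoothed_nuclear_frame), window_px >= 3)
  if (is.null(offset)) {
    rng <- diff(range(smoothed_nuclear_frame))
    if (rng == 0) return(matrix(0, nrow(smoothed_nuclear_frame),
                                ncol(smoothed_nuclear_frame)))
    offset <- offset_frac * rng
  }
  hw <- floor(window_px / 2)
  mask <- EBImage::thresh(smoothed_nuclear_frame, w = hw, h = hw,
                          offset = offset)
  mask <- EBImage::fillHull(mask)
  mk <- as.matrix(mask)
  storage.mode(mk) <- "double"
  mk
}

#' Split touching nuclei by distance-transform watershed
#'
#' Touching nuclei merge into one connected component after thresholding.
#' Because nuclei are roughly oval, the Euclidean distance transform of the
#' mask has one dome per nucleus; a watershed of the inverted distance map
#' cuts the component along the saddle between domes. Shallow spurious minima
#' (caused by boundary roughness) would over-segment, so minima whose depth
#' below their lowest saddle is less than `h_depth` are suppressed first —
#' the h-minima step. Objects forming a single catchment basin are left
#' untouched, and the foreground pixel set is preserved.
#'
#' @param mask binary matrix from [binarize_nuclei()].
#' @param h_depth minimum basin depth (in px of distance-transform height)
#'   for a cut; larger values split less.
#' @return integer label matrix (0 = background).
#' @export
split_touching <- function(mask, h_depth = 2) {
  stopifnot(is.matrix(mask))
  if (sum(mask) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = max(h_depth, sqrt(.Machine$double.eps)),
                               ext = 1)
  lm <- as.matrix(labels)
  storage.mode(lm) <- "integer"
  lm
}

#' Keep nuclei inside constrictions whole
#'
#' A nucleus squeezing through a constriction takes on a dumbbell shape with
#' two lobes, which the watershed would wrongly split into two objects. Any
#' watershed fragment whose parent connected component overlaps a row's
#' boundary band (and lies near a constriction midpoint) is therefore merged
#' back into that parent component, undoing the split locally while leaving
#' splitting active everywhere else.
#'
#' @param labels label matrix from [split_touching()].
#' @param mask the binary mask the labels were derived from.
#' @param geometry a `device_geometry`.
#' @return relabelled integer matrix.
#' @export
suppress_splitting_in_constrictions <- function(labels, mask, geometry) {
  comp <- as.matrix(EBImage::bwlabel(mask))
  storage.mode(comp) <- "integer"
  ncomp <- max(comp)
  if (ncomp == 0L) return(labels)
  out <- labels
  for (ci in seq_len(ncomp)) {
    idx <- which(comp == ci)
    labs <- unique(out[idx]); labs <- labs[labs > 0L]
    if (length(labs) < 2L) next
    bb <- pixel_bbox(idx, nrow(comp))
    if (bbox_in_constriction(bb, geometry)) {
      out[idx][out[idx] > 0L] <- labs[1L]
    }
  }
  relabel_compact(out)
}

pixel_bbox <- function(idx, H) {
  y <- (idx - 1L) %% H + 1L
  x <- (idx - 1L) %/% H + 1L
  c(min_x = min(x), min_y = min(y), max_x = max(x), max_y = max(y))
}

# TRUE if a bounding box spans a constriction boundary band: leading edge past
# the lower boundary and trailing edge not yet past the upper boundary, near a
# constriction x-midpoint (margin = half the median pillar spacing).
bbox_in_constriction <- function(bb, geometry) {
  for (rw in geometry$rows) {
    if (bb[["min_y"]] < rw$lower_boundary_y &&
        bb[["max_y"]] > rw$upper_boundary_y) {
      xc <- rw$x_centers
      if (length(xc) == 0L) return(TRUE)
      margin <- if (length(xc) >= 2L) stats::median(diff(sort(xc))) / 2 else Inf
      cx <- (bb[["min_x"]] + bb[["max_x"]]) / 2
      if (any(abs(xc - cx) <= margin)) return(TRUE)
    }
  }
  FALSE
}

relabel_compact <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) == 0L) return(labels)
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Remove objects that are not nuclei
#'
#' Deletes objects whose area falls outside the plausible nuclear range or
#' whose circularity `4 * pi * A / P^2` is below `min_circularity` (debris,
#' streaks). Objects inside a constriction band are exempt from the
#' circularity test, because a deforming nucleus is legitimately non-circular.
#' Surviving objects are relabelled compactly.
#'
#' @param labels integer label matrix.
#' @param geometry a `device_geometry` (used for the in-constriction
#'   exemption); may be `NULL` to disable the exemption.
#' @param pixel_size_um pixel calibration, um/px.
#' @param min_area_um2,max_area_um2 area bounds in square micrometres.
#' @param min_circularity minimum `4*pi*A/P^2` (1 = perfect circle).
#' @return filtered, compacted label matrix.
#' @export
filter_objects <- function(labels, geometry = NULL, pixel_size_um = 0.8,
                           min_area_um2 = 30, max_area_um2 = 600,
                           min_circularity = 0.3) {
  n <- max(labels)
  if (n == 0L) return(labels)
  fs <- EBImage::computeFeatures.shape(labels)
  area_um2 <- fs[, "s.area"] * pixel_size_um^2
  circ <- 4 * pi * fs[, "s.area"] / pmax(fs[, "s.perimeter"], 1)^2
  keep <- area_um2 >= min_area_um2 & area_um2 <= max_area_um2
  H <- nrow(labels)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (circ[i] < min_circularity) {
      exempt <- FALSE
      if (!is.null(geometry)) {
        bb <- pixel_bbox(which(labels == i), H)
        exempt <- bbox_in_constriction(bb, geometry)
      }
      if (!exempt) keep[i] <- FALSE
    }
  }
  out <- labels
  drop <- which(!keep)
  if (length(drop) > 0L) out[out %in% drop] <- 0L
  relabel_compact(out)
}

#' Measure per-nucleus properties
#'
#' For every labelled object: centroid, bounding box, area, and the mean
#' intensity of each raw fluorescence channel over the object's pixels.
#' Intensities are measured on the unsmoothed channels so that the
#' nuclear-marker / reporter ratio used for rupture detection is not biased
#' by blurring. The `in_constriction` flag records whether the bounding box
#' spans a constriction boundary band.
#'
#' @param labels integer label matrix.
#' @param raw_nuclear,raw_reporter raw channel matrices aligned with `labels`.
#' @param frame_index frame number recorded in each observation.
#' @param geometry a `device_geometry`, or `NULL` (flag then FALSE).
#' @return data.frame, one row per object: `frame`, `label`, `x`, `y`,
#'   `min_x`, `min_y`, `max_x`, `max_y` (inclusive, px), `area_px2`,
#'   `mean_nuclear`, `mean_reporter`, `in_constriction`.
#' @export
measure_objects <- function(labels, raw_nuclear, raw_reporter,
                            frame_index = 1L, geometry = NULL) {
  empty <- data.frame(frame = integer(), label = integer(),
                      x = numeric(), y = numeric(),
                      min_x = integer(), min_y = integer(),
                      max_x = integer(), max_y = integer(),
                      area_px2 = numeric(), mean_nuclear = numeric(),
                      mean_reporter = numeric(), in_constriction = logical())
  n <- max(labels)
  if (n == 0L) return(empty)
  H <- nrow(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  y <- (idx - 1L) %% H + 1L
  x <- (idx - 1L) %/% H + 1L
  cnt <- tabulate(lab, n)
  obs <- data.frame(
    frame = frame_index,
    label = seq_len(n),
    x = as.numeric(rowsum(x, lab)) / cnt,
    y = as.numeric(rowsum(y, lab)) / cnt,
    min_x = as.integer(tapply(x, lab, min)),
    min_y = as.integer(tapply(y, lab, min)),
    max_x = as.integer(tapply(x, lab, max)),
    max_y = as.integer(tapply(y, lab, max)),
    area_px2 = as.numeric(cnt),
    mean_nuclear = as.numeric(rowsum(raw_nuclear[idx], lab)) / cnt,
    mean_reporter = as.numeric(rowsum(raw_reporter[idx], lab)) / cnt,
    in_constriction = FALSE
  )
  if (!is.null(geometry)) {
    for (i in seq_len(n)) {
      bb <- c(min_x = obs$min_x[i], min_y = obs$min_y[i],
              max_x = obs$max_x[i], max_y = obs$max_y[i])
      obs$in_constriction[i] <- bbox_in_constriction(bb, geometry)
    }
  }
  obs
}

#' Segment one frame end to end
#'
#' Smoothing, adaptive thresholding, watershed splitting, in-constriction
#' split suppression, object filtering and measurement, in that order.
#'
#' @param nuclear_frame raw nuclear-marker frame.
#' @param reporter_frame raw reporter frame.
#' @param frame_index frame number for the observations.
#' @param geometry a `device_geometry` or `NULL`.
#' @param config an [analysis_config()].
#' @param threshold_offset absolute adaptive-threshold offset (see
#'   [binarize_nuclei()]); `NULL` falls back to the per-frame fraction.
#' @return list with `observations` (data.frame) and `labels` (matrix).
#' @export
segment_frame <- function(nuclear_frame, reporter_frame, frame_index,
                          geometry = NULL, config = analysis_config(),
                          threshold_offset = NULL) {
  sm <- smooth_fluorescence(nuclear_frame, sigma = config$smooth_sigma)
  mask <- binarize_nuclei(sm, window_px = config$threshold_window_px,
                          offset_frac = config$threshold_offset_frac,
                          offset = threshold_offset)
  labels <- split_touching(mask, h_depth = config$h_depth)
  if (!is.null(geometry)) {
    labels <- suppress_splitting_in_constrictions(labels, mask, geometry)
  }
  labels <- filter_objects(labels, geometry,
                           pixel_size_um = config$pixel_size_um,
                           min_area_um2 = config$min_area_um2,
                           max_area_um2 = config$max_area_um2,
                           min_circularity = config$min_circularity)
  obs <- measure_objects(labels, nuclear_frame, reporter_frame,
                         frame_index, geometry)
  list(observations = obs, labels = labels)
}
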