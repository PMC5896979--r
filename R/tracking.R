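#' Pairing cost between two nucleus observations
#'
#' The likelihood that two observations in consecutive frames are the same
#' nucleus is scored by
#' `E = distance^2 + w_intensity * |dI| + w_area * |dA|`,
#' where distance is the centroid displacement in px, `dI` the change in mean
#' nuclear-marker intensity and `dA` the change in area (px^2). Position alone
#' is ambiguous when nuclei are close together; area and chromatin-marker
#' intensity are approximately conserved for one nucleus over one interval
#' but differ between nuclei, so they disambiguate. Units are deliberately
#' mixed, matching the original formulation; the weights (default 2 and 2)
#' are exposed for tuning.
#'
#' @param a,b single-row observation data.frames (see [measure_objects()]).
#' @param w_intensity,w_area weights of the intensity and area terms.
#' @return list with `value` and components `dist2`, `d_intensity`, `d_area`.
#' @export
pairing_cost <- function(a, b, w_intensity = 2, w_area = 2) {
  d2 <- (a$x - b$x)^2 + (a$y - b$y)^2
  di <- abs(a$mean_nuclear - b$mean_nuclear)
  da <- abs(a$area_px2 - b$area_px2)
  list(value = d2 + w_intensity * di + w_area * da,
       dist2 = d2, d_intensity = di, d_area = da)
}

#' Link observations between two consecutive frames
#'
#' Candidate pairs are restricted to centroid displacements of at most
#' `max_distance_um` (the farthest a cell plausibly travels in one frame
#' interval). Pairs are then accepted greedily: the available pair with the
#' lowest cost is linked and both members become unavailable, repeating until
#' no admissible pair remains. Ties are broken by lexicographic
#' `(prev, curr)` index order.
#'
#' @param prev,curr observation data.frames for frames t-1 and t.
#' @param max_distance_um gating distance in micrometres.
#' @param pixel_size_um pixel calibration, um/px.
#' @param w_intensity,w_area cost weights, see [pairing_cost()].
#' @return list with `pairs` (2-column matrix of row indices into `prev` and
#'   `curr`), `unmatched_prev`, `unmatched_curr` (integer vectors).
#' @export
link_frames <- function(prev, curr, max_distance_um = 40, pixel_size_um = 0.8,
                        w_intensity = 2, w_area = 2) {
  np <- nrow(prev); nc <- nrow(curr)
  if (np == 0L || nc == 0L) {
    return(list(pairs = matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("prev", "curr"))),
                unmatched_prev = seq_len(np), unmatched_curr = seq_len(nc)))
  }
  gate_px <- max_distance_um / pixel_size_um
  d2 <- outer(prev$x, curr$x, "-")^2 + outer(prev$y, curr$y, "-")^2
  di <- abs(outer(prev$mean_nuclear, curr$mean_nuclear, "-"))
  da <- abs(outer(prev$area_px2, curr$area_px2, "-"))
  E <- d2 + w_intensity * di + w_area * da
  adm <- which(d2 <= gate_px^2, arr.ind = TRUE)
  if (nrow(adm) == 0L) {
    return(list(pairs = matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("prev", "curr"))),
                unmatched_prev = seq_len(np), unmatched_curr = seq_len(nc)))
  }
  e <- E[adm]
  ord <- order(e, adm[, 1L], adm[, 2L])
  adm <- adm[ord, , drop = FALSE]
  p_free <- rep(TRUE, np); c_free <- rep(TRUE, nc)
  pairs <- matrix(integer(), 0, 2)
  for (k in seq_len(nrow(adm))) {
    i <- adm[k, 1L]; j <- adm[k, 2L]
    if (p_free[i] && c_free[j]) {
      pairs <- rbind(pairs, c(i, j))
      p_free[i] <- FALSE; c_free[j] <- FALSE
    }
  }
  colnames(pairs) <- c("prev", "curr")
  list(pairs = pairs,
       unmatched_prev = which(p_free),
       unmatched_curr = which(c_free))
}

#' Assemble tracks from per-frame observations
#'
#' Runs [link_frames()] over consecutive frames. Every object in the first
#' frame starts a track; unmatched objects in later frames start new tracks;
#' a track with no match in the next frame ends (no gap closing — linking is
#' strictly frame-to-frame).
#'
#' @param per_frame_observations list of observation data.frames, one per
#'   frame (may be empty data.frames), or a single data.frame with a `frame`
#'   column covering frames `1..T`.
#' @param n_frames_total total number of frames `T` (required when a single
#'   data.frame is given and trailing frames are empty).
#' @inheritParams link_frames
#' @return list with `observations` (data.frame of all observations plus a
#'   `track_id` column) and `tracks` (data.frame `track_id`, `start_frame`,
#'   `end_frame`, `n_obs`, `parent_id`).
#' @export
build_tracks <- function(per_frame_observations, n_frames_total = NULL,
                         max_distance_um = 40, pixel_size_um = 0.8,
                         w_intensity = 2, w_area = 2) {
  if (is.data.frame(per_frame_observations)) {
    df <- per_frame_observations
    T <- if (is.null(n_frames_total)) max(df$frame, 1L) else n_frames_total
    per_frame_observations <- lapply(seq_len(T), function(t) {
      df[df$frame == t, , drop = FALSE]
    })
  }
  T <- length(per_frame_observations)
  next_id <- 1L
  all_obs <- list()
  track_ids <- vector("list", T)
  for (t in seq_len(T)) {
    obs <- per_frame_observations[[t]]
    nids <- integer(nrow(obs))
    if (t == 1L || length(track_ids[[t - 1L]]) == 0L || nrow(obs) == 0L) {
      link <- NULL
    } else {
      link <- link_frames(per_frame_observations[[t - 1L]], obs,
                          max_distance_um, pixel_size_um,
                          w_intensity, w_area)
    }
    if (!is.null(link) && nrow(link$pairs) > 0L) {
      nids[link$pairs[, "curr"]] <- track_ids[[t - 1L]][link$pairs[, "prev"]]
    }
    if (any(nids == 0L)) {
      fresh <- which(nids == 0L)
      nids[fresh] <- next_id + seq_along(fresh) - 1L
      next_id <- next_id + length(fresh)
    }
    track_ids[[t]] <- nids
    if (nrow(obs) > 0L) {
      obs$track_id <- nids
      all_obs[[t]] <- obs
    }
  }
  obs_df <- if (length(all_obs) > 0L) do.call(rbind, all_obs) else
    cbind(measure_objects(matrix(0L, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1))[0, ],
          data.frame(track_id = integer()))
  rownames(obs_df) <- NULL
  if (nrow(obs_df) > 0L) {
    agg_start <- tapply(obs_df$frame, obs_df$track_id, min)
    agg_end <- tapply(obs_df$frame, obs_df$track_id, max)
    agg_n <- tapply(obs_df$frame, obs_df$track_id, length)
    ids <- as.integer(names(agg_start))
    tracks <- data.frame(track_id = ids,
                         start_frame = as.integer(agg_start),
                         end_frame = as.integer(agg_end),
                         n_obs = as.integer(agg_n),
                         parent_id = NA_integer_)
    tracks <- tracks[order(tracks$track_id), , drop = FALSE]
    rownames(tracks) <- NULL
  } else {
    tracks <- data.frame(track_id = integer(), start_frame = integer(),
                         end_frame = integer(), n_obs = integer(),
                         parent_id = integer())
  }
  list(observations = obs_df, tracks = tracks)
}
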