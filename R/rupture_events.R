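#' Nuclear-marker / reporter ratio series of a track
#'
#' Nuclear envelope rupture lets the nucleoplasmic reporter (e.g. NLS-GFP)
#' escape into the cytoplasm, so its mean nuclear intensity drops, while the
#' chromatin marker (e.g. H2B-tdTomato) is unaffected. The ratio
#' `r_t = mean_nuclear / mean_reporter` therefore rises sharply at rupture
#' and decays back as the envelope is repaired and the reporter re-imported.
#' Because both channels bleach together, the ratio also cancels
#' photobleaching and global illumination changes.
#'
#' @param track_obs observation data.frame of one track.
#' @return data.frame `(frame, ratio, delta)` with `delta[1] = NA`; frames
#'   with zero reporter signal are dropped with a warning.
#' @export
compute_ratio_series <- function(track_obs) {
  track_obs <- track_obs[order(track_obs$frame), , drop = FALSE]
  bad <- track_obs$mean_reporter <= 0
  if (any(bad)) {
    warning(sprintf("%d frame(s) with non-positive reporter signal skipped",
                    sum(bad)))
    track_obs <- track_obs[!bad, , drop = FALSE]
  }
  r <- track_obs$mean_nuclear / track_obs$mean_reporter
  data.frame(frame = track_obs$frame, ratio = r,
             delta = c(NA_real_, diff(r)))
}

#' Detect rupture start frames in a ratio series
#'
#' Two triggers mark the onset of nuclear envelope rupture: a *jump*, where
#' the ratio increases by more than `jump_frac` (default 20%) of its value at
#' the previous time point in a single interval, and a *sustained rise*,
#' where the ratio increases strictly over at least `rise_len` (default 5)
#' consecutive time points — the signature of a slow reporter leak. A
#' sustained-rise event starts at the first frame of the monotone run.
#' Triggers that fall inside an already-flagged rise are merged into one
#' start.
#'
#' A step counts toward a rise only if it gains at least `min_rise_frac` of
#' the previous ratio. Raw camera intensities are integer counts, so on real
#' data a flat trace produces ties that break strictly increasing runs; on
#' continuous-valued data the rank-only rule would eventually fire on any
#' flat noisy trace (an ascending run of 5 has probability 1/120 per
#' window), and runs of noise upticks leading into a jump would drag the
#' start frame early. The per-step floor restores the intended behaviour;
#' set it to 0 for the literal rank-only rule.
#'
#' @param series data.frame from [compute_ratio_series()].
#' @param jump_frac single-interval relative increase that triggers a start.
#' @param rise_len length of a strictly increasing run that triggers a start.
#' @param min_rise_frac minimum per-step relative increase for a step to
#'   count as part of a sustained rise.
#' @return data.frame `(frame, trigger)`; `trigger` is `"jump"` or
#'   `"sustained_rise"`.
#' @export
detect_rupture_start <- function(series, jump_frac = 0.20, rise_len = 5L,
                                 min_rise_frac = 0.01) {
  empty <- data.frame(frame = integer(), trigger = character())
  n <- nrow(series)
  if (n < 2L) return(empty)
  starts <- list()
  # jump rule
  jump_at <- which(series$delta[-1L] > jump_frac * series$ratio[-n]) + 1L
  for (i in jump_at) {
    starts[[length(starts) + 1L]] <-
      data.frame(frame = series$frame[i], idx = i, trigger = "jump")
  }
  # sustained strictly increasing run (each step a genuine increase)
  inc <- series$delta[-1L] > min_rise_frac * series$ratio[-n]
  run <- rle(inc)
  pos <- cumsum(c(1L, run$lengths))
  for (k in seq_along(run$lengths)) {
    if (run$values[k] && run$lengths[k] >= rise_len - 1L) {
      i0 <- pos[k]  # first frame of the rise
      starts[[length(starts) + 1L]] <-
        data.frame(frame = series$frame[i0], idx = i0,
                   trigger = "sustained_rise")
    }
  }
  if (length(starts) == 0L) return(empty)
  st <- do.call(rbind, starts)
  st <- st[order(st$idx, st$trigger), , drop = FALSE]
  # merge triggers belonging to one rise: keep a start only if the ratio
  # dropped back below the running level since the previous kept start
  kept <- st[1L, , drop = FALSE]
  for (i in seq_len(nrow(st))[-1L]) {
    prev_idx <- kept$idx[nrow(kept)]
    between <- series$delta[(prev_idx + 1L):st$idx[i]]
    if (any(between < 0, na.rm = TRUE)) {
      kept <- rbind(kept, st[i, ])
    }
  }
  data.frame(frame = kept$frame, trigger = kept$trigger,
             stringsAsFactors = FALSE)
}

#' Find the end of a rupture event
#'
#' Repair re-imports the reporter, bringing the ratio back down. The event
#' ends at the first frame after the ratio peak at which the ratio has
#' returned close to its pre-rupture baseline (within `baseline_tol_frac`)
#' and the frame-to-frame change has settled to approximately zero. If no
#' such frame exists before the series ends, the event is left open
#' (`NA`) and is excluded from duration statistics.
#'
#' @param series data.frame from [compute_ratio_series()].
#' @param start_frame rupture start frame.
#' @param baseline_tol_frac allowed excess over baseline at closure.
#' @param delta_zero_tol |delta| considered "returned to zero", as a fraction
#'   of the baseline ratio.
#' @return list with `end_frame` (or `NA`), `baseline_ratio`, `peak_frame`.
#' @export
detect_rupture_end <- function(series, start_frame, baseline_tol_frac = 0.10,
                               delta_zero_tol = 0.05) {
  i0 <- match(start_frame, series$frame)
  stopifnot(!is.na(i0))
  baseline <- if (i0 > 1L) series$ratio[i0 - 1L] else series$ratio[i0]
  n <- nrow(series)
  departed <- FALSE
  ipk <- i0
  if (i0 < n) {
    for (i in i0:n) {
      if (series$ratio[i] > series$ratio[ipk]) ipk <- i
      if (series$ratio[i] > (1 + baseline_tol_frac) * baseline) {
        departed <- TRUE
      } else if (departed && i > i0 &&
                 abs(series$delta[i]) <= delta_zero_tol * baseline) {
        return(list(end_frame = series$frame[i], baseline_ratio = baseline,
                    peak_frame = series$frame[ipk]))
      }
    }
  }
  list(end_frame = NA_integer_, baseline_ratio = baseline,
       peak_frame = series$frame[ipk])
}

#' Detect rupture events for all tracks
#'
#' Applies [detect_rupture_start()] and [detect_rupture_end()] per track and
#' enforces that no event starts while another event of the same track is
#' still open (such triggers are part of the same rupture and are merged).
#'
#' @param observations tracked observation data.frame.
#' @param frame_interval_min minutes per frame.
#' @param jump_frac,rise_len,min_rise_frac see [detect_rupture_start()].
#' @param baseline_tol_frac,delta_zero_tol see [detect_rupture_end()].
#' @return data.frame: `track_id`, `start_frame`, `end_frame`,
#'   `duration_min`, `trigger`, `baseline_ratio`.
#' @export
detect_ruptures <- function(observations, frame_interval_min,
                            jump_frac = 0.20, rise_len = 5L,
                            min_rise_frac = 0.01,
                            baseline_tol_frac = 0.10, delta_zero_tol = 0.05) {
  empty <- data.frame(track_id = integer(), start_frame = integer(),
                      end_frame = integer(), duration_min = numeric(),
                      trigger = character(), baseline_ratio = numeric())
  out <- list()
  for (tdf in split(observations, observations$track_id)) {
    series <- suppressWarnings(compute_ratio_series(tdf))
    starts <- detect_rupture_start(series, jump_frac, rise_len, min_rise_frac)
    open_until <- -Inf
    for (i in seq_len(nrow(starts))) {
      sf <- starts$frame[i]
      if (sf <= open_until) next  # still inside the previous event
      e <- detect_rupture_end(series, sf, baseline_tol_frac, delta_zero_tol)
      out[[length(out) + 1L]] <- data.frame(
        track_id = tdf$track_id[1L],
        start_frame = sf,
        end_frame = if (is.na(e$end_frame)) NA_integer_ else e$end_frame,
        duration_min = if (is.na(e$end_frame)) NA_real_ else
          (e$end_frame - sf) * frame_interval_min,
        trigger = starts$trigger[i],
        baseline_ratio = e$baseline_ratio)
      open_until <- if (is.na(e$end_frame)) Inf else e$end_frame
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reclassify ruptures coinciding with cell division as mitosis
#'
#' Nuclear envelope breakdown at mitosis also releases the reporter and is
#' initially indistinguishable from interphase rupture. The two are told
#' apart by what happens next: after division a new nucleus appears next to
#' the old one. A candidate rupture is reclassified as mitosis when a new
#' track begins within `mitosis_window` frames of the rupture start, with its
#' first centroid within `vicinity_um` of the candidate nucleus.
#'
#' @param observations tracked observation data.frame.
#' @param tracks track summary data.frame from [build_tracks()].
#' @param candidate_ruptures data.frame from [detect_ruptures()].
#' @param vicinity_um search radius for a daughter nucleus, micrometres.
#' @param pixel_size_um pixel calibration.
#' @param mitosis_window frames after the rupture start in which the daughter
#'   must appear.
#' @return list with `ruptures` (surviving events), `mitoses` (data.frame
#'   `parent_track_id`, `daughter_track_ids` comma-joined, `division_frame`)
#'   and `tracks` (with `parent_id` filled for daughters).
#' @export
reclassify_mitosis <- function(observations, tracks, candidate_ruptures,
                               vicinity_um = 40, pixel_size_um = 0.8,
                               mitosis_window = 1L) {
  mit <- data.frame(parent_track_id = integer(), daughter_track_ids = character(),
                    division_frame = integer())
  if (nrow(candidate_ruptures) == 0L) {
    return(list(ruptures = candidate_ruptures, mitoses = mit, tracks = tracks))
  }
  vic_px <- vicinity_um / pixel_size_um
  is_mitosis <- logical(nrow(candidate_ruptures))
  for (i in seq_len(nrow(candidate_ruptures))) {
    tid <- candidate_ruptures$track_id[i]
    sf <- candidate_ruptures$start_frame[i]
    parent_obs <- observations[observations$track_id == tid &
                                 observations$frame == sf, , drop = FALSE]
    if (nrow(parent_obs) == 0L) next
    new_tracks <- tracks[tracks$track_id != tid &
                           tracks$start_frame >= sf &
                           tracks$start_frame <= sf + mitosis_window, ,
                         drop = FALSE]
    daughters <- integer(0)
    for (nt in new_tracks$track_id) {
      first <- observations[observations$track_id == nt, , drop = FALSE]
      first <- first[which.min(first$frame), , drop = FALSE]
      d <- sqrt((first$x - parent_obs$x)^2 + (first$y - parent_obs$y)^2)
      if (d <= vic_px) daughters <- c(daughters, nt)
    }
    if (length(daughters) > 0L) {
      is_mitosis[i] <- TRUE
      div_frame <- min(tracks$start_frame[tracks$track_id %in% daughters]) - 1L
      mit <- rbind(mit, data.frame(
        parent_track_id = tid,
        daughter_track_ids = paste(daughters, collapse = ";"),
        division_frame = div_frame))
      tracks$parent_id[tracks$track_id %in% daughters] <- tid
    }
  }
  list(ruptures = candidate_ruptures[!is_mitosis, , drop = FALSE],
       mitoses = mit, tracks = tracks)
}

#' Normalize a rupture ratio trace for population averaging
#'
#' Re-expresses the ratio relative to its value immediately before rupture
#' (`t = 0`) and scales so the peak equals 1:
#' `s_t = (r_t - r_0) / (r_peak - r_0)`. This puts traces from nuclei with
#' different baseline ratios and rupture magnitudes on a common axis, so
#' repair kinetics can be averaged across cells.
#'
#' @param series data.frame from [compute_ratio_series()].
#' @param start_frame rupture start frame.
#' @param end_frame final frame to include (defaults to end of series).
#' @return data.frame `(frame, t_min_relative = frame - t0, value)` where the
#'   row at `t = 0` has value 0 and the peak row has value 1.
#' @export
normalize_rupture_trace <- function(series, start_frame, end_frame = NULL) {
  i0 <- match(start_frame, series$frame)
  stopifnot(!is.na(i0))
  ib <- max(i0 - 1L, 1L)  # t = 0: last pre-rupture frame
  iend <- if (is.null(end_frame)) nrow(series) else match(end_frame, series$frame)
  r <- series$ratio[ib:iend]
  r0 <- r[1L]
  pk <- max(r)
  stopifnot(pk > r0)
  data.frame(frame = series$frame[ib:iend],
             t_rel = series$frame[ib:iend] - series$frame[ib],
             value = (r - r0) / (pk - r0))
}
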