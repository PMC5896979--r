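# Evaluation against generator ground truth: detection scores, identity-link
# accuracy and event matching. Used by the validation suites.

#' Score per-frame detections against scripted nuclei
#'
#' A detection matches a true nucleus of the same frame when their centroids
#' are within `tol_px`; matching is greedy by distance, one-to-one.
#'
#' @param observations observation data.frame (detected).
#' @param truth_tracks ground-truth data.frame `(id, frame, x, y)`.
#' @param tol_px centroid match tolerance, px.
#' @return list with `recall`, `precision`, and the per-detection `matches`
#'   data.frame `(frame, label, true_id)`.
#' @export
score_detections <- function(observations, truth_tracks, tol_px = 5) {
  matches <- list()
  n_true <- 0L; n_det <- nrow(observations); n_hit <- 0L
  for (t in sort(unique(c(observations$frame, truth_tracks$frame)))) {
    det <- observations[observations$frame == t, , drop = FALSE]
    tru <- truth_tracks[truth_tracks$frame == t, , drop = FALSE]
    n_true <- n_true + nrow(tru)
    if (nrow(det) == 0L || nrow(tru) == 0L) next
    d <- sqrt(outer(det$x, tru$x, "-")^2 + outer(det$y, tru$y, "-")^2)
    cand <- which(d <= tol_px, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    cand <- cand[order(d[cand]), , drop = FALSE]
    du <- rep(TRUE, nrow(det)); tu <- rep(TRUE, nrow(tru))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (du[i] && tu[j]) {
        du[i] <- FALSE; tu[j] <- FALSE; n_hit <- n_hit + 1L
        matches[[length(matches) + 1L]] <- data.frame(
          frame = t, label = det$label[i],
          track_id = if (is.null(det$track_id)) NA_integer_ else det$track_id[i],
          true_id = tru$id[j])
      }
    }
  }
  m <- if (length(matches) > 0L) do.call(rbind, matches) else
    data.frame(frame = integer(), label = integer(), track_id = integer(),
               true_id = integer())
  list(recall = if (n_true > 0L) n_hit / n_true else NA_real_,
       precision = if (n_det > 0L) n_hit / n_det else NA_real_,
       matches = m)
}

#' Fraction of true identity links preserved by tracking
#'
#' A ground-truth link is a pair of consecutive-frame observations of the
#' same scripted nucleus. The link is reproduced when both endpoints were
#' detected (within `tol_px`) and carry the same track id.
#'
#' @param observations tracked observation data.frame (with `track_id`).
#' @param truth_tracks ground-truth `(id, frame, x, y)` data.frame.
#' @param tol_px centroid match tolerance, px.
#' @return fraction in `[0, 1]`.
#' @export
link_accuracy <- function(observations, truth_tracks, tol_px = 5) {
  sc <- score_detections(observations, truth_tracks, tol_px)
  m <- sc$matches
  n_links <- 0L; n_ok <- 0L
  for (id in unique(truth_tracks$id)) {
    fr <- sort(truth_tracks$frame[truth_tracks$id == id])
    consec <- fr[which(diff(fr) == 1L)]
    for (f in consec) {
      n_links <- n_links + 1L
      a <- m[m$true_id == id & m$frame == f, , drop = FALSE]
      b <- m[m$true_id == id & m$frame == f + 1L, , drop = FALSE]
      if (nrow(a) == 1L && nrow(b) == 1L &&
          !is.na(a$track_id) && a$track_id == b$track_id) {
        n_ok <- n_ok + 1L
      }
    }
  }
  if (n_links == 0L) return(NA_real_)
  n_ok / n_links
}

#' Match detected transit events against scripted truth
#'
#' A detected event matches a truth event when both refer to the same
#' scripted nucleus (via centroid matching at the entry frame), the same
#' row, the same outcome, and entry/exit frames agree within
#' `frame_tol`.
#'
#' @param transits detected transit events.
#' @param observations tracked observations (to resolve track -> nucleus).
#' @param truth list with `transits` and `tracks` tables from the generator.
#' @param frame_tol allowed entry/exit frame deviation.
#' @return list with `recall`, `precision`, `n_true`, `n_det`,
#'   `max_time_err_frames` (largest |entry/exit error| over matches).
#' @export
score_transits <- function(transits, observations, truth, frame_tol = 1L) {
  tru <- truth$transits
  sc <- score_detections(observations, truth$tracks, tol_px = 6)
  # map track_id -> dominant true id
  m <- sc$matches
  track_map <- vapply(split(m$true_id, m$track_id), function(v) {
    as.integer(names(sort(table(v), decreasing = TRUE))[1L])
  }, integer(1))
  det <- transits
  det$true_id <- track_map[as.character(det$track_id)]
  used <- rep(FALSE, nrow(tru))
  hit <- 0L; max_err <- 0
  for (i in seq_len(nrow(det))) {
    j <- which(!used & tru$id == det$true_id[i] &
                 tru$row_index == det$row_index[i] &
                 tru$outcome == det$outcome[i] &
                 abs(tru$entry_frame - det$entry_frame[i]) <= frame_tol &
                 abs(tru$exit_frame - det$exit_frame[i]) <= frame_tol)
    if (length(j) > 0L) {
      used[j[1L]] <- TRUE; hit <- hit + 1L
      max_err <- max(max_err,
                     abs(tru$entry_frame[j[1L]] - det$entry_frame[i]),
                     abs(tru$exit_frame[j[1L]] - det$exit_frame[i]))
    }
  }
  list(recall = if (nrow(tru) > 0L) hit / nrow(tru) else NA_real_,
       precision = if (nrow(det) > 0L) hit / nrow(det) else NA_real_,
       n_true = nrow(tru), n_det = nrow(det),
       max_time_err_frames = max_err)
}

#' Match detected rupture events against scripted truth
#'
#' @param ruptures detected rupture events.
#' @param observations tracked observations.
#' @param truth generator truth (needs `ruptures` and `tracks`).
#' @param frame_tol allowed start/end frame deviation.
#' @return list with `recall` (over truth rows expected detected),
#'   `n_false_positive` (events on nuclei not scripted to rupture),
#'   `max_duration_err_frames`.
#' @export
score_ruptures <- function(ruptures, observations, truth, frame_tol = 1L) {
  tru <- truth$ruptures
  sc <- score_detections(observations, truth$tracks, tol_px = 6)
  m <- sc$matches
  track_map <- vapply(split(m$true_id, m$track_id), function(v) {
    as.integer(names(sort(table(v), decreasing = TRUE))[1L])
  }, integer(1))
  det <- ruptures
  det$true_id <- track_map[as.character(det$track_id)]
  expected <- tru[tru$expected_detected, , drop = FALSE]
  hit <- 0L; max_err <- 0; n_fp <- 0L
  used <- rep(FALSE, nrow(expected))
  for (i in seq_len(nrow(det))) {
    j <- which(!used & expected$id == det$true_id[i] &
                 abs(expected$start_frame - det$start_frame[i]) <= frame_tol)
    if (length(j) > 0L) {
      used[j[1L]] <- TRUE; hit <- hit + 1L
      if (!is.na(expected$end_frame[j[1L]]) && !is.na(det$end_frame[i])) {
        derr <- abs((expected$end_frame[j[1L]] - expected$start_frame[j[1L]]) -
                      (det$end_frame[i] - det$start_frame[i]))
        max_err <- max(max_err, derr)
      }
    } else if (!isTRUE(det$true_id[i] %in% tru$id)) {
      n_fp <- n_fp + 1L
    }
  }
  list(recall = if (nrow(expected) > 0L) hit / nrow(expected) else NA_real_,
       n_false_positive = n_fp,
       max_duration_err_frames = max_err)
}
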