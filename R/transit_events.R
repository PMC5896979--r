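#' Classify a nucleus relative to one constriction row
#'
#' With migration toward decreasing y ("up"), a nucleus is *attempting* to
#' pass when the leading (top) edge of its bounding box has crossed the lower
#' boundary while the trailing (bottom) edge has not yet cleared the upper
#' boundary; it has *passed* when the trailing edge is above the upper
#' boundary; otherwise it is still *outside* on the entry side. With
#' `migration_direction = "down"` the roles of the edges and boundaries are
#' mirrored.
#'
#' @param obs single observation row (needs `min_y`, `max_y`).
#' @param row one element of `geometry$rows`.
#' @param migration_direction `"up"` (decreasing y, default) or `"down"`.
#' @return one of `"outside"`, `"attempting"`, `"passed"`.
#' @export
constriction_state <- function(obs, row, migration_direction = "up") {
  if (migration_direction == "up") {
    if (obs$max_y < row$upper_boundary_y) return("passed")
    if (obs$min_y < row$lower_boundary_y && obs$max_y > row$upper_boundary_y) {
      return("attempting")
    }
    "outside"
  } else {
    if (obs$min_y > row$lower_boundary_y) return("passed")
    if (obs$max_y > row$upper_boundary_y && obs$min_y < row$lower_boundary_y) {
      return("attempting")
    }
    "outside"
  }
}

#' Detect constriction-transit events along one track
#'
#' Runs the attempt / success / failure state machine per constriction row:
#' an attempt starts at the first `attempting` frame; it ends as a *success*
#' when the nucleus fully clears the far boundary, as a *failure* when it
#' backs out on the entry side, or as *ongoing* if the track ends
#' mid-attempt. Attempts whose attempting streak lasts exactly one time point
#' are discarded — these are grazes by cells moving parallel to the row, not
#' true transit attempts. A nucleus spanning two rows is evaluated
#' independently against each.
#'
#' The transit time convention is `(exit_frame - entry_frame) *
#' frame_interval_min`, with entry the first attempting frame and exit the
#' frame at which the outcome is decided.
#'
#' @param track_obs observation data.frame of one track, ordered by frame.
#' @param geometry a `device_geometry`.
#' @param frame_interval_min minutes per frame.
#' @param migration_direction `"up"` or `"down"`.
#' @return data.frame: `track_id`, `row_index`, `entry_frame`, `exit_frame`,
#'   `outcome` (success/failure/ongoing), `transit_time_min`,
#'   `adjacent_to_previous` (TRUE when the attempt begins no later than one
#'   frame after its predecessor ended — the back-and-forth case that manual
#'   analysts may read as one long attempt).
#' @export
detect_transits <- function(track_obs, geometry, frame_interval_min,
                            migration_direction = "up") {
  empty <- data.frame(track_id = integer(), row_index = integer(),
                      entry_frame = integer(), exit_frame = integer(),
                      outcome = character(), transit_time_min = numeric(),
                      adjacent_to_previous = logical())
  if (nrow(track_obs) < 2L) return(empty)
  track_obs <- track_obs[order(track_obs$frame), , drop = FALSE]
  tid <- track_obs$track_id[1L]
  events <- list()
  for (ri in seq_along(geometry$rows)) {
    rw <- geometry$rows[[ri]]
    states <- vapply(seq_len(nrow(track_obs)), function(i) {
      constriction_state(track_obs[i, ], rw, migration_direction)
    }, character(1))
    frames <- track_obs$frame
    in_attempt <- FALSE; entry <- NA_integer_; n_att <- 0L
    last_exit <- NA_integer_
    for (i in seq_along(states)) {
      s <- states[i]
      if (!in_attempt) {
        if (s == "attempting") {
          in_attempt <- TRUE; entry <- frames[i]; n_att <- 1L
        }
      } else {
        if (s == "attempting") {
          n_att <- n_att + 1L
        } else {
          outcome <- if (s == "passed") "success" else "failure"
          if (n_att > 1L) {
            events[[length(events) + 1L]] <- data.frame(
              track_id = tid, row_index = ri,
              entry_frame = entry, exit_frame = frames[i],
              outcome = outcome,
              transit_time_min = (frames[i] - entry) * frame_interval_min,
              adjacent_to_previous = isTRUE(entry - last_exit <= 1L))
            last_exit <- frames[i]
          }
          in_attempt <- FALSE; entry <- NA_integer_; n_att <- 0L
          # a failure frame can immediately begin a new approach; a passed
          # nucleus is outside the band and re-entry is caught as attempting
        }
      }
    }
    if (in_attempt && n_att > 1L) {
      events[[length(events) + 1L]] <- data.frame(
        track_id = tid, row_index = ri,
        entry_frame = entry, exit_frame = frames[length(frames)],
        outcome = "ongoing", transit_time_min = NA_real_,
        adjacent_to_previous = isTRUE(entry - last_exit <= 1L))
    }
  }
  if (length(events) == 0L) return(empty)
  out <- do.call(rbind, events)
  out[order(out$row_index, out$entry_frame), , drop = FALSE]
}

#' Detect transit events for all tracks
#'
#' @param observations data.frame of tracked observations (with `track_id`).
#' @inheritParams detect_transits
#' @return combined event data.frame (see [detect_transits()]).
#' @export
detect_all_transits <- function(observations, geometry, frame_interval_min,
                                migration_direction = "up") {
  parts <- lapply(split(observations, observations$track_id), detect_transits,
                  geometry = geometry, frame_interval_min = frame_interval_min,
                  migration_direction = migration_direction)
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- detect_transits(data.frame(frame = integer(), track_id = integer()),
                           geometry, frame_interval_min)
  }
  rownames(out) <- NULL
  out
}
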