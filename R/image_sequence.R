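#' Calibrated multi-channel time-lapse sequence
#'
#' An `image_sequence` bundles a T-frame, C-channel image stack with the two
#' calibration values every downstream measurement depends on: the pixel size
#' (micrometres per pixel) and the frame interval (minutes). Frames are stored
#' as a 4-D numeric array with dimensions `(y, x, channel, frame)`; pixel
#' indices are 1-based, `y` increases downward.
#'
#' The three canonical channels are the transmitted-light image of the device
#' (used for registration and drift estimation), a chromatin marker such as
#' H2B-tdTomato (used for segmentation and tracking), and a nucleoplasmic
#' reporter such as NLS-GFP (used for nuclear envelope rupture detection).
#'
#' @param frames numeric array, `H x W x C x T`, or `H x W x C` for a single
#'   frame (a trailing frame dimension is added).
#' @param pixel_size_um pixel size in micrometres per pixel; must be positive.
#' @param frame_interval_min time between frames in minutes; must be positive.
#' @param channel_names character vector of length C. Defaults to
#'   `c("transmitted", "nuclear", "reporter")` when C = 3.
#' @return an object of class `image_sequence`.
#' @export
image_sequence <- function(frames, pixel_size_um, frame_interval_min,
                           channel_names = NULL) {
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 4L)
  if (is.null(channel_names)) {
    channel_names <- if (dim(frames)[3L] == 3L) {
      c("transmitted", "nuclear", "reporter")
    } else {
      paste0("channel", seq_len(dim(frames)[3L]))
    }
  }
  stopifnot(
    length(channel_names) == dim(frames)[3L],
    is.numeric(pixel_size_um), pixel_size_um > 0,
    is.numeric(frame_interval_min), frame_interval_min > 0,
    dim(frames)[4L] >= 1L
  )
  structure(
    list(frames = frames,
         pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min,
         channel_names = as.character(channel_names)),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "image_sequence: %d frame(s), %d channel(s) [%s], %d x %d px\n",
    d[4L], d[3L], paste(x$channel_names, collapse = ", "), d[1L], d[2L]))
  cat(sprintf("  pixel size %.4g um/px, frame interval %.4g min\n",
              x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

#' Number of frames in a sequence
#' @param sequence an `image_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(sequence) dim(sequence$frames)[4L]

#' Extract one channel of one frame
#'
#' @param sequence an `image_sequence`.
#' @param frame frame index (1-based).
#' @param channel channel name or index.
#' @return numeric matrix `H x W`.
#' @export
get_frame <- function(sequence, frame, channel) {
  ch <- channel_index(sequence, channel)
  sequence$frames[, , ch, frame]
}

channel_index <- function(sequence, channel) {
  if (is.character(channel)) {
    ch <- match(channel, sequence$channel_names)
    if (is.na(ch)) {
      stop(sprintf("channel '%s' not present (have: %s)", channel,
                   paste(sequence$channel_names, collapse = ", ")),
           call. = FALSE)
    }
    ch
  } else {
    as.integer(channel)
  }
}
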