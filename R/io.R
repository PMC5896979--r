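#' Write an image sequence as a multi-page TIFF with a JSON sidecar
#'
#' Pages are written in the requested axis order (`"TCYX"`: all channels of
#' frame 1, then frame 2, ...; `"CTYX"`: all frames of channel 1, then
#' channel 2, ...) as 32-bit float TIFF. A `<path>.json` sidecar records the
#' axis order, channel names, pixel size and frame interval so the stack can
#' be read back without guessing.
#'
#' @param sequence an [image_sequence()].
#' @param path output TIFF path.
#' @param axes page order, `"TCYX"` (default) or `"CTYX"`.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(sequence, path, axes = c("TCYX", "CTYX")) {
  axes <- match.arg(axes)
  d <- dim(sequence$frames)
  pages <- list()
  if (axes == "TCYX") {
    for (t in seq_len(d[4L])) for (c in seq_len(d[3L])) {
      pages[[length(pages) + 1L]] <- sequence$frames[, , c, t]
    }
  } else {
    for (c in seq_len(d[3L])) for (t in seq_len(d[4L])) {
      pages[[length(pages) + 1L]] <- sequence$frames[, , c, t]
    }
  }
  pages <- lapply(pages, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(axes = axes, n_frames = d[4L], n_channels = d[3L],
               height = d[1L], width = d[2L],
               channel_names = sequence$channel_names,
               pixel_size_um = sequence$pixel_size_um,
               frame_interval_min = sequence$frame_interval_min)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack into an image sequence
#'
#' Axis order and calibration are taken from the `<path>.json` sidecar
#' written by [write_sequence()] when present; otherwise they must be given
#' explicitly. An error is raised if a requested channel name is missing.
#'
#' @param path TIFF path.
#' @param channel_map optional character vector renaming the channels, or
#'   names to require (error if absent after naming).
#' @param pixel_size_um,frame_interval_min calibration overrides (required
#'   if no sidecar).
#' @param axes,n_channels layout overrides (required if no sidecar).
#' @return an [image_sequence()].
#' @export
read_sequence <- function(path, channel_map = NULL, pixel_size_um = NULL,
                          frame_interval_min = NULL, axes = NULL,
                          n_channels = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list()
  }
  axes <- axes %||% meta$axes
  n_channels <- n_channels %||% meta$n_channels
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  frame_interval_min <- frame_interval_min %||% meta$frame_interval_min
  if (is.null(axes) || is.null(n_channels)) {
    stop("axis order / channel count unknown: no sidecar and no override given",
         call. = FALSE)
  }
  if (is.null(pixel_size_um) || is.null(frame_interval_min)) {
    stop("pixel_size_um and frame_interval_min must come from the sidecar or arguments",
         call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  C <- as.integer(n_channels)
  T <- length(pages) / C
  if (T != floor(T)) stop("page count not divisible by channel count",
                          call. = FALSE)
  T <- as.integer(T)
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  frames <- array(0, dim = c(H, W, C, T))
  k <- 1L
  if (axes == "TCYX") {
    for (t in seq_len(T)) for (c in seq_len(C)) {
      frames[, , c, t] <- pages[[k]]; k <- k + 1L
    }
  } else if (axes == "CTYX") {
    for (c in seq_len(C)) for (t in seq_len(T)) {
      frames[, , c, t] <- pages[[k]]; k <- k + 1L
    }
  } else {
    stop("unsupported axis order: ", axes, call. = FALSE)
  }
  cn <- meta$channel_names %||% NULL
  seq <- image_sequence(frames, pixel_size_um, frame_interval_min, cn)
  if (!is.null(channel_map)) {
    missing <- setdiff(channel_map, seq$channel_names)
    if (length(missing) > 0L && length(channel_map) != length(seq$channel_names)) {
      stop(sprintf("channel '%s' not present in stack", missing[1L]),
           call. = FALSE)
    }
    if (length(channel_map) == length(seq$channel_names)) {
      seq$channel_names <- as.character(channel_map)
    }
  }
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a
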