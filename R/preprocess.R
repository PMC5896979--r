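#' Gaussian smoothing of a fluorescence frame
#'
#' Suppresses camera noise before adaptive thresholding. The kernel has
#' sigma = 2.5 px, chosen so that its effective support matches a 10 x 10 px
#' window; smoothing conserves total intensity away from borders. Smoothed
#' images are used only to build segmentation masks — reported intensities
#' are always measured on the raw channels.
#'
#' @param frame numeric matrix, single fluorescence frame.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same dimensions.
#' @export
smooth_fluorescence <- function(frame, sigma = 2.5) {
  stopifnot(is.matrix(frame))
  as.matrix(EBImage::gblur(frame, sigma = sigma))
}

#' Estimate the integer-pixel shift between two frames
#'
#' Returns the translation `(dx, dy)` such that `frame(x, y)` best matches
#' `reference(x - dx, y - dy)`, i.e. the displacement of `frame` relative to
#' `reference`. A fast FFT cross-correlation of the mean-subtracted images
#' proposes a candidate lag, which is then refined by exact normalized
#' cross-correlation (Pearson correlation over the overlap region) on a small
#' neighbourhood of lags. For noise-free integer translations the estimate is
#' exact.
#'
#' @param frame,reference numeric matrices of identical dimensions.
#' @param max_shift largest |dx|, |dy| considered, px.
#' @return integer vector `c(dx, dy)`.
#' @export
estimate_shift <- function(frame, reference, max_shift = 20) {
  stopifnot(all(dim(frame) == dim(reference)))
  if (stats::sd(frame) == 0 || stats::sd(reference) == 0) {
    warning("flat image: cannot estimate shift, returning (0, 0)")
    return(c(dx = 0L, dy = 0L))
  }
  H <- nrow(frame); W <- ncol(frame)
  ph <- stats::nextn(H + 2 * max_shift, 2)
  pw <- stats::nextn(W + 2 * max_shift, 2)
  a <- matrix(0, ph, pw); b <- matrix(0, ph, pw)
  a[1:H, 1:W] <- frame - mean(frame)
  b[1:H, 1:W] <- reference - mean(reference)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  lag_y <- c(0:max_shift, (ph - max_shift):(ph - 1)) # wrap-around indexing
  lag_x <- c(0:max_shift, (pw - max_shift):(pw - 1))
  sub <- cc[lag_y + 1L, lag_x + 1L]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  to_lag <- function(i, n) { l <- c(0:max_shift, -(max_shift:1))[i]; l }
  dy0 <- to_lag(pk[1L], ph); dx0 <- to_lag(pk[2L], pw)

  # refine with exact NCC on the overlap in a +/-3 window
  best <- c(dx0, dy0); best_r <- -Inf
  for (dy in max(-max_shift, dy0 - 3):min(max_shift, dy0 + 3)) {
    for (dx in max(-max_shift, dx0 - 3):min(max_shift, dx0 + 3)) {
      r <- overlap_ncc(frame, reference, dx, dy)
      if (!is.na(r) && r > best_r) { best_r <- r; best <- c(dx, dy) }
    }
  }
  c(dx = as.integer(best[1L]), dy = as.integer(best[2L]))
}

# Pearson correlation of frame against reference shifted by (dx, dy),
# computed over the overlapping region only.
overlap_ncc <- function(frame, reference, dx, dy) {
  H <- nrow(frame); W <- ncol(frame)
  ys <- max(1, 1 + dy):min(H, H + dy)   # rows of frame
  xs <- max(1, 1 + dx):min(W, W + dx)
  if (length(ys) < 2 || length(xs) < 2) return(NA_real_)
  f <- frame[ys, xs]
  g <- reference[ys - dy, xs - dx]
  if (stats::sd(f) == 0 || stats::sd(g) == 0) return(NA_real_)
  stats::cor(as.vector(f), as.vector(g))
}

#' Estimate a drift trace for a whole sequence
#'
#' Stage drift is estimated frame-to-frame on the transmitted-light channel
#' (whose content — the device itself — is stationary) by normalized
#' cross-correlation between each frame and its predecessor, then accumulated
#' into offsets relative to frame 1. Per-frame estimates larger than
#' `max_shift` are clamped with a warning.
#'
#' @param sequence an [image_sequence()].
#' @param channel channel used for registration; default `"transmitted"`.
#' @param max_shift maximum per-frame drift in px.
#' @return data.frame `(frame, dx, dy)`; row 1 is `(0, 0)`.
#' @export
estimate_drift <- function(sequence, channel = "transmitted", max_shift = 20) {
  T <- n_frames(sequence)
  dx <- integer(T); dy <- integer(T)
  if (T > 1L) {
    for (t in 2:T) {
      s <- estimate_shift(get_frame(sequence, t, channel),
                          get_frame(sequence, t - 1L, channel),
                          max_shift = max_shift)
      if (any(abs(s) >= max_shift)) {
        warning(sprintf("frame %d: drift estimate at clamp limit (%d px)",
                        t, max_shift))
        s <- pmin(pmax(s, -max_shift), max_shift)
      }
      dx[t] <- dx[t - 1L] + s[["dx"]]
      dy[t] <- dy[t - 1L] + s[["dy"]]
    }
  }
  data.frame(frame = seq_len(T), dx = dx, dy = dy)
}

#' Undo stage drift
#'
#' Translates every channel of frame t by `-(dx_t, dy_t)` so all frames share
#' frame 1's coordinate system. The identical integer translation is applied
#' to all channels of a frame; uncovered margins are filled with the
#' per-channel median.
#'
#' @param sequence an [image_sequence()].
#' @param drift data.frame from [estimate_drift()]; one row per frame.
#' @return stabilized `image_sequence`.
#' @export
stabilize <- function(sequence, drift) {
  stopifnot(nrow(drift) == n_frames(sequence))
  fr <- sequence$frames
  for (t in seq_len(dim(fr)[4L])) {
    dx <- drift$dx[t]; dy <- drift$dy[t]
    if (dx == 0L && dy == 0L) next
    for (c in seq_len(dim(fr)[3L])) {
      m <- fr[, , c, t]
      fr[, , c, t] <- translate_frame(m, -dx, -dy, fill = stats::median(m))
    }
  }
  sequence$frames <- fr
  sequence
}

# Integer translation: out(x, y) = in(x - dx, y - dy), fill outside.
translate_frame <- function(m, dx, dy, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  if (length(ys) > 0 && length(xs) > 0) out[ys, xs] <- m[ys - dy, xs - dx]
  out
}
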