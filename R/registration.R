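#' Integer-pixel translational stack registration
#'
#' Registers every frame to the first by maximising the circular
#' cross-correlation (computed via FFT), then applies the integer shift and
#' fills the vacated margin with the frame's median as a background estimate.
#' Translation only: the statistic downstream (per-cell PCC) operates on
#' pixel grids, so sub-pixel or rotational refinement is deliberately
#' omitted. An all-constant frame, for which the correlation is undefined, is
#' flagged and passed through with zero shift.
#'
#' @param frames 3-D array `[H, W, T]` of frames, or a `timelapse_stack`
#'   (then `channel` selects the registered channel).
#' @param channel Channel to register when `frames` is a stack.
#' @return List with `frames` (registered array `[H, W, T]`) and `shifts`
#'   (data frame `frame, dy, dx, flagged`). Shifts are the corrections that
#'   were applied: a frame equal to frame 1 rolled by `(+3, -2)` yields a
#'   recovered shift of `(-3, +2)`.
#' @export
register_translation <- function(frames, channel = 1L) {
  if (inherits(frames, "timelapse_stack")) {
    frames <- frames$data[, , channel, , drop = TRUE]
    if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  }
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 1)
  if (dim(frames)[3] < 2L) {
    if (dim(frames)[3] == 0L) stop("empty stack")
  }
  h <- dim(frames)[1]
  w <- dim(frames)[2]
  nt <- dim(frames)[3]
  ref <- frames[, , 1]
  ref_c <- ref - mean(ref)
  ref_sd <- sd(as.numeric(ref))
  Fr <- stats::fft(ref_c)
  shifts <- data.frame(
    frame = seq_len(nt), dy = 0L, dx = 0L, flagged = FALSE
  )
  out <- frames
  for (t in seq_len(nt)) {
    if (t == 1) next
    fr <- frames[, , t]
    if (ref_sd == 0 || sd(as.numeric(fr)) == 0) {
      shifts$flagged[t] <- TRUE
      next
    }
    cc <- Re(stats::fft(Fr * Conj(stats::fft(fr - mean(fr))),
      inverse = TRUE
    ))
    idx <- which.max(cc)
    dy <- (idx - 1) %% h
    dx <- (idx - 1) %/% h
    if (dy > h / 2) dy <- dy - h
    if (dx > w / 2) dx <- dx - w
    shifts$dy[t] <- as.integer(dy)
    shifts$dx[t] <- as.integer(dx)
    out[, , t] <- roll_fill(fr, dy, dx)
  }
  list(frames = out, shifts = shifts)
}

# Apply an integer roll out[i, j] = img[i - dy, j - dx] and fill the vacated
# margin with the image median.
roll_fill <- function(img, dy, dx) {
  h <- nrow(img)
  w <- ncol(img)
  fill <- median(img)
  ri <- ((seq_len(h) - 1 - dy) %% h) + 1
  ci <- ((seq_len(w) - 1 - dx) %% w) + 1
  out <- img[ri, ci, drop = FALSE]
  if (dy > 0) out[seq_len(min(dy, h)), ] <- fill
  if (dy < 0) out[seq(max(1, h + dy + 1), h), ] <- fill
  if (dx > 0) out[, seq_len(min(dx, w))] <- fill
  if (dx < 0) out[, seq(max(1, w + dx + 1), w)] <- fill
  out
}

#' Log-transform and background-subtract an image
#'
#' Intensity equalisation applied before probability mapping: the image is
#' log-transformed (`log(1 + I)`, order matters: log first), a smooth
#' background is estimated by a large-sigma Gaussian blur of the
#' log-transformed image, subtracted, and the result clipped at zero. This
#' compresses the dynamic range so that per-cell brightness heterogeneity and
#' global intensity drifts largely cancel.
#'
#' @param image Non-negative numeric matrix.
#' @param background_scale Gaussian sigma of the background estimate, px.
#' @return Matrix of the same size, non-negative.
#' @export
log_background_subtract <- function(image, background_scale = 20) {
  stopifnot(background_scale > 0)
  if (min(image) < 0) stop("image must be non-negative")
  l <- log1p(image)
  bg <- gauss_blur(l, background_scale)
  pmax(l - bg, 0)
}
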