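#' Extract region mean-intensity curves from a FLIP stack
#'
#' Per-time-point mean intensity over the bleach and reference regions
#' (square regions given in micrometres, centre + side). For stacks with
#' several planes in the channel dimension, `z_mode = "max"` takes the
#' maximum-intensity projection before averaging, `"single"` uses one plane.
#'
#' @param stack A `timelapse_stack` (FLIP series).
#' @param bleach_region,reference_region Lists `x_um, y_um, side_um`
#'   (square centre and side).
#' @param z_mode `"max"` or `"single"`.
#' @param z_plane Plane used when `z_mode = "single"`.
#' @return Data frame `frame, t_s, bleach, reference`.
#' @export
extract_region_means <- function(stack, bleach_region, reference_region,
                                 z_mode = c("single", "max"), z_plane = 1L) {
  z_mode <- match.arg(z_mode)
  ps <- stack$pixel_size
  h <- dim(stack$data)[1]
  w <- dim(stack$data)[2]
  region_idx <- function(region) {
    half <- region$side_um / 2
    jj <- which((seq_len(w) - 0.5) * ps >= region$x_um - half &
      (seq_len(w) - 0.5) * ps <= region$x_um + half)
    ii <- which((seq_len(h) - 0.5) * ps >= region$y_um - half &
      (seq_len(h) - 0.5) * ps <= region$y_um + half)
    if (!length(ii) || !length(jj)) stop("empty region")
    if (min(region$x_um - half, region$y_um - half) < 0 ||
      region$x_um + half > w * ps || region$y_um + half > h * ps) {
      stop("region outside image")
    }
    list(ii = ii, jj = jj)
  }
  bi <- region_idx(bleach_region)
  ri <- region_idx(reference_region)
  nt <- n_frames(stack)
  bm <- numeric(nt)
  rm_ <- numeric(nt)
  for (t in seq_len(nt)) {
    img <- if (z_mode == "max") {
      apply(stack$data[, , , t, drop = FALSE], c(1, 2), max)
    } else {
      stack$data[, , z_plane, t]
    }
    bm[t] <- mean(img[bi$ii, bi$jj])
    rm_[t] <- mean(img[ri$ii, ri$jj])
  }
  data.frame(
    frame = seq_len(nt), t_s = (seq_len(nt) - 1) * stack$frame_interval,
    bleach = bm, reference = rm_
  )
}

#' Bleach-correct and normalise a FLIP curve
#'
#' Correction follows the unbleached-control convention: the raw reference
#' curve is divided by the control curve (itself normalised to its
#' pre-bleach value), removing acquisition bleaching; when no control cell
#' is available, a mono-exponential acquisition-bleach model fitted to the
#' pre-bleach frames is used instead. The corrected curve is then divided by
#' its value at `prebleach_index`, so the normalised signal equals 1 exactly
#' at the last pre-bleach time point. Normalisation is invariant to a global
#' intensity scaling of the raw stack.
#'
#' @param raw Numeric vector of raw reference-region means.
#' @param control Optional control-cell curve on the same time grid.
#' @param prebleach_index Index of the last pre-bleach time point.
#' @param times Optional time vector (s), required for the exponential-fit
#'   correction; defaults to `0:(length(raw) - 1)`.
#' @param method `"control"` (requires `control`) or `"expfit"`.
#' @param cell_id Optional identifier carried through.
#' @return Data frame of class `flip_curve`: `cell_id, frame, t_s, raw,
#'   corrected, normalised`, with attribute `prebleach_index`.
#' @export
correct_and_normalize <- function(raw, control = NULL, prebleach_index,
                                  times = NULL,
                                  method = c("control", "expfit"),
                                  cell_id = NA) {
  method <- match.arg(method)
  n <- length(raw)
  if (prebleach_index < 1 || prebleach_index > n) {
    stop("prebleach_index out of range")
  }
  if (is.null(times)) times <- seq_len(n) - 1
  if (method == "control") {
    if (is.null(control)) stop("control curve required for method 'control'")
    stopifnot(length(control) == n)
    if (any(control <= 0)) stop("control value <= 0")
    ctrl_n <- control / control[prebleach_index]
  } else {
    pre <- seq_len(prebleach_index)
    if (prebleach_index >= 3 && all(raw[pre] > 0)) {
      fit <- lm(log(raw[pre]) ~ times[pre])
      # acquisition bleaching can only dim the signal
      k <- min(unname(coef(fit)[2]), 0)
    } else {
      k <- 0
    }
    ctrl_n <- exp(k * (times - times[prebleach_index]))
  }
  corrected <- raw / ctrl_n
  if (corrected[prebleach_index] <= 0) {
    stop("non-positive corrected value at prebleach_index")
  }
  normalised <- corrected / corrected[prebleach_index]
  out <- data.frame(
    cell_id = cell_id, frame = seq_len(n), t_s = times,
    raw = raw, corrected = corrected, normalised = normalised
  )
  attr(out, "prebleach_index") <- prebleach_index
  class(out) <- c("flip_curve", "data.frame")
  out
}

#' Aggregate normalised FLIP curves across cells
#'
#' Pointwise mean of the normalised signal over cells with a 95% confidence
#' band (`mean +/- 1.96 * SE`); the single-cell curves are retained for
#' overlay plotting.
#'
#' @param curves List of `flip_curve` objects (or data frames with `t_s` and
#'   `normalised`) on a common time grid.
#' @return List of class `flip_aggregate`: `summary` (data frame
#'   `t_s, mean, ci_lo, ci_hi, n`), `curves` (input list).
#' @export
aggregate_flip <- function(curves) {
  if (!length(curves)) stop("empty input")
  t0 <- curves[[1]]$t_s
  for (cu in curves) {
    if (length(cu$t_s) != length(t0) || any(cu$t_s != t0)) {
      stop("curves must share a common time grid")
    }
  }
  mat <- vapply(curves, function(cu) cu$normalised, numeric(length(t0)))
  mat <- matrix(mat, nrow = length(t0))
  m <- rowMeans(mat)
  n <- ncol(mat)
  se <- if (n > 1) apply(mat, 1, sd) / sqrt(n) else rep(0, length(t0))
  structure(
    list(
      summary = data.frame(
        t_s = t0, mean = m,
        ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se, n = n
      ),
      curves = curves
    ),
    class = "flip_aggregate"
  )
}

#' Plot aggregated FLIP curves
#'
#' Thick mean line with a 95% confidence band and the single-cell curves
#' dotted underneath.
#'
#' @param x A `flip_aggregate` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.flip_aggregate <- function(x, ...) {
  s <- x$summary
  plot(s$t_s, s$mean,
    type = "n", ylim = range(0, 1.1, s$ci_hi),
    xlab = "time (s)", ylab = "normalised intensity", ...
  )
  for (cu in x$curves) {
    graphics::lines(cu$t_s, cu$normalised, lty = 3, col = "grey60")
  }
  graphics::lines(s$t_s, s$ci_lo, col = "steelblue", lty = 2)
  graphics::lines(s$t_s, s$ci_hi, col = "steelblue", lty = 2)
  graphics::lines(s$t_s, s$mean, col = "steelblue", lwd = 2)
  invisible(x)
}
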