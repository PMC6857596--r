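#' Time-averaged mean square displacement of trajectories
#'
#' For each particle, `MSD(tau) = mean over all valid t of
#' |r(t + tau) - r(t)|^2` with overlapping windows (all start times), for
#' `tau = 1 .. lag_max` frames. Only pairs whose both endpoints were
#' observed contribute, so gapped trajectories contribute fewer pairs; for a
#' gapless track `n_pairs(tau) = n_frames - tau`.
#'
#' @param trajectories Data frame `particle_id, frame, x_um, y_um` (one or
#'   many particles). For a single trajectory `lag_max` must be smaller than
#'   the trajectory length; for grouped input the lag grid of each particle
#'   is capped at its length minus one.
#' @param lag_max Maximum lag in frames (default 40).
#' @param frame_interval Frame interval, s; taken from the input attribute
#'   when present.
#' @return Data frame `particle_id, lag_frames, lag_s, msd_um2, n_pairs`.
#' @export
time_avg_msd <- function(trajectories, lag_max = 40,
                         frame_interval = attr(trajectories, "frame_interval") %||% 1) {
  stopifnot(all(c("particle_id", "frame", "x_um", "y_um") %in% names(trajectories)))
  ids <- unique(trajectories$particle_id)
  single <- length(ids) == 1L
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    tr <- trajectories[trajectories$particle_id == ids[k], ]
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    if (single && lag_max >= n) {
      stop("lag_max must be smaller than the trajectory length")
    }
    lmax <- min(lag_max, n - 1)
    if (lmax < 1) next
    frames <- tr$frame
    msd <- numeric(lmax)
    np <- integer(lmax)
    for (tau in seq_len(lmax)) {
      j <- match(frames + tau, frames)
      ok <- !is.na(j)
      np[tau] <- sum(ok)
      if (np[tau] > 0) {
        dx <- tr$x_um[j[ok]] - tr$x_um[ok]
        dy <- tr$y_um[j[ok]] - tr$y_um[ok]
        msd[tau] <- mean(dx * dx + dy * dy)
      } else {
        msd[tau] <- NA_real_
      }
    }
    out[[k]] <- data.frame(
      particle_id = ids[k], lag_frames = seq_len(lmax),
      lag_s = seq_len(lmax) * frame_interval,
      msd_um2 = msd, n_pairs = np
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(
      particle_id = integer(), lag_frames = integer(), lag_s = numeric(),
      msd_um2 = numeric(), n_pairs = integer()
    )
  }
  attr(res, "frame_interval") <- frame_interval
  res
}

#' Ensemble average and per-lag histogram of time-averaged MSD curves
#'
#' The ensemble curve is the per-lag mean over particles of their
#' time-averaged MSDs (per-particle averaging). The histogram matrix counts
#' particles per (lag, MSD-bin) for colour-coded population plots; column
#' sums equal the number of particles at every lag.
#'
#' @param curves Data frame from [time_avg_msd()]; all particles must share
#'   one lag grid.
#' @param n_bins Number of MSD bins for the histogram.
#' @param breaks Optional explicit bin breaks (um^2).
#' @return List of class `ensemble_msd`: `ensemble` (data frame
#'   `lag_frames, lag_s, msd_um2, n_particles`), `hist` (matrix
#'   `n_bins x n_lags`), `breaks`.
#' @export
ensemble_msd <- function(curves, n_bins = 30, breaks = NULL) {
  if (nrow(curves) == 0) stop("at least one curve required")
  lags <- sort(unique(curves$lag_frames))
  ids <- unique(curves$particle_id)
  tab <- table(curves$particle_id)
  if (length(unique(as.integer(tab))) != 1L ||
    as.integer(tab[1]) != length(lags)) {
    stop("inconsistent lag grids across particles")
  }
  sp <- split(curves$msd_um2, curves$lag_frames)
  ens <- vapply(sp, mean, numeric(1))
  npart <- vapply(sp, length, integer(1))
  fi <- attr(curves, "frame_interval") %||%
    (curves$lag_s[1] / curves$lag_frames[1])
  if (is.null(breaks)) {
    top <- max(curves$msd_um2, 0)
    if (top <= 0) top <- 1e-12
    breaks <- seq(0, top * 1.000001, length.out = n_bins + 1)
  }
  hist_mat <- matrix(0L, length(breaks) - 1, length(lags))
  for (li in seq_along(lags)) {
    v <- curves$msd_um2[curves$lag_frames == lags[li]]
    hist_mat[, li] <- as.integer(
      table(cut(v, breaks, include.lowest = TRUE))
    )
  }
  rownames(hist_mat) <- NULL
  colnames(hist_mat) <- lags
  structure(
    list(
      ensemble = data.frame(
        lag_frames = lags, lag_s = lags * fi,
        msd_um2 = as.numeric(ens), n_particles = as.integer(npart)
      ),
      hist = hist_mat, breaks = breaks, n_particles = length(ids)
    ),
    class = "ensemble_msd"
  )
}

#' Estimate a diffusion coefficient from an ensemble MSD curve
#'
#' Fits `MSD(tau) = 4 D tau + b` by least squares over the requested lag
#' range and returns `D = slope / 4` together with the intercept `b`
#' (`b = 4 sigma_loc^2` for a static localisation error).
#'
#' @param ensemble An `ensemble_msd` object or its `ensemble` data frame.
#' @param lag_range Inclusive frame-lag range used for the fit.
#' @return List `D_um2_s`, `intercept_um2`, `slope_um2_s`.
#' @export
fit_msd_diffusion <- function(ensemble, lag_range = c(1, 10)) {
  df <- if (inherits(ensemble, "ensemble_msd")) ensemble$ensemble else ensemble
  sel <- df$lag_frames >= lag_range[1] & df$lag_frames <= lag_range[2]
  stopifnot(sum(sel) >= 2)
  fit <- lm(msd_um2 ~ lag_s, data = df[sel, ])
  slope <- unname(coef(fit)[2])
  list(
    D_um2_s = slope / 4,
    intercept_um2 = unname(coef(fit)[1]),
    slope_um2_s = slope
  )
}

#' Plot an ensemble MSD histogram
#'
#' Colour-coded particle counts per (lag, MSD bin) with the ensemble- and
#' time-averaged mean overlaid as a dotted line.
#'
#' @param x An `ensemble_msd` object.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.ensemble_msd <- function(x, ...) {
  lags <- x$ensemble$lag_s
  mids <- (head(x$breaks, -1) + tail(x$breaks, -1)) / 2
  graphics::image(lags, mids, t(x$hist),
    col = grDevices::hcl.colors(64, "viridis"),
    xlab = "lag (s)", ylab = expression(MSD ~ (mu * m^2)), ...
  )
  graphics::lines(lags, x$ensemble$msd_um2, lty = 3, lwd = 2, col = "white")
  invisible(x)
}
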