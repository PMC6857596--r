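#' Detect bright particles in a single frame
#'
#' Spot detection emulating a Mosaic-style tracker: a band-pass
#' (difference-of-Gaussians) response is computed at `sigma`, local maxima
#' within `radius_px` are found, maxima below `quality_cutoff` discarded, and
#' surviving peaks refined to sub-pixel positions by an intensity-weighted
#' centroid of the positive response in the peak's window. The cutoff is an
#' absolute response value; by default it adapts to the frame as eight
#' robust standard deviations (MAD) of the response.
#'
#' @param frame Single registered frame (numeric matrix).
#' @param radius_px Particle radius, px (>= 1).
#' @param quality_cutoff Absolute response cutoff; `NULL` for the adaptive
#'   default.
#' @param sigma Band-pass scale, px; defaults to `radius_px / 2`.
#' @return Data frame `x_px, y_px, intensity` (pixel-centre convention,
#'   0-based coordinates: a spot centred on pixel `(i, j)` is at
#'   `(j + 0.5, i + 0.5)`).
#' @export
detect_particles <- function(frame, radius_px = 4, quality_cutoff = NULL,
                             sigma = radius_px / 2) {
  stopifnot(radius_px >= 1)
  resp <- gauss_blur(frame, sigma) - gauss_blur(frame, 2 * sigma)
  if (is.null(quality_cutoff)) {
    quality_cutoff <- 8 * mad(as.numeric(resp))
  }
  size <- 2L * as.integer(ceiling(radius_px)) + 1L
  mx <- EBImage::dilate(resp, EBImage::makeBrush(size, "disc"))
  peaks <- which(resp >= mx & resp > quality_cutoff, arr.ind = TRUE)
  if (nrow(peaks) == 0) {
    return(data.frame(
      x_px = numeric(), y_px = numeric(), intensity = numeric()
    ))
  }
  h <- nrow(frame)
  w <- ncol(frame)
  r <- as.integer(ceiling(radius_px))
  out <- matrix(0, nrow(peaks), 3)
  for (k in seq_len(nrow(peaks))) {
    i <- peaks[k, 1]
    j <- peaks[k, 2]
    i0 <- max(1L, i - r)
    i1 <- min(h, i + r)
    j0 <- max(1L, j - r)
    j1 <- min(w, j + r)
    wgt <- pmax(resp[i0:i1, j0:j1, drop = FALSE], 0)
    sw <- sum(wgt)
    ys <- (i0:i1) - 0.5
    xs <- (j0:j1) - 0.5
    out[k, 1] <- sum(rowSums(t(wgt) * xs)) / sw
    out[k, 2] <- sum(rowSums(wgt * ys)) / sw
    out[k, 3] <- resp[i, j]
  }
  data.frame(x_px = out[, 1], y_px = out[, 2], intensity = out[, 3])
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate matches
#' between active track heads and current detections are accepted in order
#' of increasing squared distance, matches beyond `max_displacement_px` are
#' forbidden, and a track may bridge up to `gap_max` missing frames before
#' it terminates. Each detection joins at most one trajectory; unmatched
#' detections start new tracks. Positions are converted to micrometres at
#' link time.
#'
#' @param detections Data frame `frame, x_px, y_px` (all frames pooled), or
#'   a list of per-frame data frames `x_px, y_px`.
#' @param max_displacement_px Maximum per-link displacement, px.
#' @param gap_max Maximum number of bridged missing frames.
#' @param pixel_size Pixel size, um/px.
#' @param frame_interval Frame interval, s (stored as an attribute).
#' @param labels Optional integer label matrix; each trajectory is assigned
#'   the cell label under its first detection.
#' @return Data frame `particle_id, frame, x_um, y_um, cell_label` with
#'   attributes `pixel_size` and `frame_interval`.
#' @export
link_tracks <- function(detections, max_displacement_px = 2, gap_max = 3,
                        pixel_size = 1, frame_interval = 1, labels = NULL) {
  if (is.list(detections) && !is.data.frame(detections)) {
    detections <- do.call(rbind, lapply(seq_along(detections), function(f) {
      d <- detections[[f]]
      if (nrow(d) == 0) {
        return(NULL)
      }
      cbind(frame = f, d)
    }))
    if (is.null(detections)) {
      detections <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric())
    }
  }
  stopifnot(all(c("frame", "x_px", "y_px") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  tracks <- list() # each: list(points = matrix(frame, x, y), last_frame)
  active <- integer(0)
  maxd2 <- max_displacement_px^2
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    nd <- nrow(det)
    # retire stale tracks
    if (length(active)) {
      last <- vapply(tracks[active], function(t) t$last_frame, numeric(1))
      active <- active[f - last <= gap_max + 1]
    }
    assigned_det <- rep(FALSE, nd)
    assigned_trk <- rep(FALSE, length(active))
    if (nd > 0 && length(active) > 0) {
      hx <- vapply(tracks[active], function(t) t$x, numeric(1))
      hy <- vapply(tracks[active], function(t) t$y, numeric(1))
      cost <- outer(hx, det$x_px, "-")^2 + outer(hy, det$y_px, "-")^2
      repeat {
        m <- which.min(cost)
        if (!length(m) || cost[m] > maxd2) break
        ti <- (m - 1) %% length(active) + 1
        di <- (m - 1) %/% length(active) + 1
        id <- active[ti]
        tracks[[id]]$points[[length(tracks[[id]]$points) + 1]] <-
          c(f, det$x_px[di], det$y_px[di])
        tracks[[id]]$last_frame <- f
        tracks[[id]]$x <- det$x_px[di]
        tracks[[id]]$y <- det$y_px[di]
        assigned_det[di] <- TRUE
        assigned_trk[ti] <- TRUE
        cost[ti, ] <- Inf
        cost[, di] <- Inf
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- list(
        points = list(c(f, det$x_px[di], det$y_px[di])),
        last_frame = f, x = det$x_px[di], y = det$y_px[di]
      )
      active <- c(active, length(tracks))
    }
  }
  if (!length(tracks)) {
    out <- data.frame(
      particle_id = integer(), frame = integer(),
      x_um = numeric(), y_um = numeric(), cell_label = integer()
    )
  } else {
    rows <- lapply(seq_along(tracks), function(id) {
      p <- do.call(rbind, tracks[[id]]$points)
      data.frame(
        particle_id = id, frame = as.integer(p[, 1]),
        x_um = p[, 2] * pixel_size, y_um = p[, 3] * pixel_size
      )
    })
    out <- do.call(rbind, rows)
    out$cell_label <- NA_integer_
    if (!is.null(labels)) {
      first <- out[!duplicated(out$particle_id), ]
      for (k in seq_len(nrow(first))) {
        i <- pmin(pmax(floor(first$y_um[k] / pixel_size), 0), nrow(labels) - 1) + 1
        j <- pmin(pmax(floor(first$x_um[k] / pixel_size), 0), ncol(labels) - 1) + 1
        out$cell_label[out$particle_id == first$particle_id[k]] <-
          labels[i, j]
      }
    }
  }
  attr(out, "pixel_size") <- pixel_size
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Track-retention filter
#'
#' Retains trajectories observed in strictly more than `min_frames` frames —
#' the retention rule used for MSD analysis (default 160 of 300-frame
#' movies; 95 is the analogous rule for 100-frame movies). Idempotent and
#' order-preserving.
#'
#' @param trajectories Data frame with `particle_id` and `frame`.
#' @param min_frames Strict lower bound on observed positions.
#' @return The filtered data frame (attributes preserved).
#' @export
filter_tracks <- function(trajectories, min_frames = 160) {
  counts <- table(trajectories$particle_id)
  keep <- names(counts)[counts > min_frames]
  out <- trajectories[as.character(trajectories$particle_id) %in% keep, ,
    drop = FALSE
  ]
  attr(out, "pixel_size") <- attr(trajectories, "pixel_size")
  attr(out, "frame_interval") <- attr(trajectories, "frame_interval")
  rownames(out) <- NULL
  out
}
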