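#' Segment cells from a preprocessed phloxine image
#'
#' Thresholds the preprocessed (log-transformed, background-subtracted)
#' phloxine image with Otsu's method to get the bright structures (live-cell
#' outlines and dead-cell fills), fills outline holes to obtain cell
#' footprints, takes the enclosed interiors (plus morphologically opened
#' dead-cell cores) as seeds, and expands seeds to the cell outline with
#' seeded region growing (`EBImage::propagate`, the CellProfiler propagate
#' algorithm). Touching cells are separated because each contributes its own
#' interior seed. Components smaller than `min_area_px` are rejected as
#' debris; border-touching cells can be excluded.
#'
#' @param phloxine_pre Preprocessed phloxine image (see
#'   [log_background_subtract()]).
#' @param pixel_size Pixel size, um/px.
#' @param min_area_px Minimum seed area; default is the area of a 2-um disc
#'   at `pixel_size`.
#' @param exclude_border Drop cells whose mask touches the image border.
#' @return List with `labels` (integer label matrix, 0 = background) and
#'   `cells` (data frame: `label, x_px, y_px, area_px, length_um, width_um,
#'   on_border, is_dead` with `is_dead` initialised to `NA`). No cells found
#'   yields an empty table, not an error.
#' @export
segment_cells <- function(phloxine_pre, pixel_size,
                          min_area_px = NULL, exclude_border = TRUE) {
  stopifnot(pixel_size > 0)
  if (is.null(min_area_px)) {
    min_area_px <- pi * (1 / pixel_size)^2
  }
  h <- nrow(phloxine_pre)
  w <- ncol(phloxine_pre)
  empty <- list(
    labels = matrix(0L, h, w),
    cells = data.frame(
      label = integer(), x_px = numeric(), y_px = numeric(),
      area_px = integer(), length_um = numeric(), width_um = numeric(),
      on_border = logical(), is_dead = logical()
    )
  )
  mx <- max(phloxine_pre)
  if (!is.finite(mx) || mx <= 0) {
    return(empty)
  }
  th <- EBImage::otsu(EBImage::Image(phloxine_pre / mx), range = c(0, 1)) * mx
  bright <- phloxine_pre > th
  if (!any(bright)) {
    return(empty)
  }
  filled <- EBImage::imageData(EBImage::fillHull(
    matrix(as.integer(bright), h, w)
  )) > 0
  interior <- filled & !bright
  # dead-cell cores: opening removes thin rims but keeps filled interiors
  open_r <- max(2L, as.integer(round(0.3 / pixel_size)))
  cores <- EBImage::imageData(EBImage::opening(
    matrix(as.integer(bright), h, w),
    EBImage::makeBrush(2L * open_r + 1L, "disc")
  )) > 0
  seeds_mask <- interior | cores
  seeds <- EBImage::imageData(EBImage::bwlabel(
    matrix(as.integer(seeds_mask), h, w)
  ))
  # reject small seeds (debris)
  areas <- tabulate(seeds[seeds > 0])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) {
    return(empty)
  }
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  seeds_new <- matrix(0L, h, w)
  pos <- seeds > 0
  seeds_new[pos] <- relab[seeds[pos]]
  labels <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(phloxine_pre / mx),
    seeds = EBImage::Image(seeds_new),
    mask = matrix(as.numeric(filled), h, w),
    lambda = 1e-4
  ))
  labels <- matrix(as.integer(round(labels)), h, w)
  recs <- list()
  out_labels <- matrix(0L, h, w)
  new_id <- 0L
  for (lab in seq_along(keep)) {
    mask <- labels == lab
    area <- sum(mask)
    if (area < max(min_area_px, 4)) next
    idx <- which(mask, arr.ind = TRUE)
    on_border <- any(idx[, 1] == 1 | idx[, 1] == h |
      idx[, 2] == 1 | idx[, 2] == w)
    if (exclude_border && on_border) next
    mm <- measure_cell(mask, pixel_size)
    new_id <- new_id + 1L
    out_labels[mask] <- new_id
    recs[[new_id]] <- data.frame(
      label = new_id,
      x_px = mean(idx[, 2]) - 0.5, y_px = mean(idx[, 1]) - 0.5,
      area_px = area,
      length_um = mm[["length_um"]], width_um = mm[["width_um"]],
      on_border = on_border, is_dead = NA
    )
  }
  if (new_id == 0L) {
    return(empty)
  }
  list(labels = out_labels, cells = do.call(rbind, recs))
}

#' Flag dead cells from their interior phloxine intensity
#'
#' A cell is dead iff the median preprocessed phloxine intensity over its
#' eroded interior exceeds an adaptive threshold: a two-class Otsu split of
#' the per-cell medians, accepted only when the upper class is at least
#' `min_separation` times brighter than the lower (so an all-live population
#' is never split); with fewer than five cells a fixed fallback threshold is
#' used. Dead cells stay in the table, flagged, and are excluded from all
#' downstream statistics.
#'
#' @param seg Segmentation result from [segment_cells()].
#' @param phloxine_pre The same preprocessed phloxine image.
#' @param pixel_size Pixel size, um/px.
#' @param min_separation Minimum upper/lower class intensity ratio for the
#'   adaptive split to be trusted.
#' @param fallback_threshold Absolute threshold used when fewer than five
#'   cells are present; defaults to half the image maximum.
#' @return `seg` with `cells$is_dead` filled in and
#'   `cells$interior_median` added.
#' @export
classify_dead <- function(seg, phloxine_pre, pixel_size,
                          min_separation = 3,
                          fallback_threshold = NULL) {
  cells <- seg$cells
  if (nrow(cells) == 0) {
    return(seg)
  }
  h <- nrow(phloxine_pre)
  w <- ncol(phloxine_pre)
  er_r <- max(2L, as.integer(round(0.3 / pixel_size)))
  brush <- EBImage::makeBrush(2L * er_r + 1L, "disc")
  med <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    mask <- seg$labels == cells$label[i]
    core <- EBImage::imageData(EBImage::erode(
      matrix(as.integer(mask), h, w), brush
    )) > 0
    if (!any(core)) core <- mask
    med[i] <- median(phloxine_pre[core])
  }
  cells$interior_median <- med
  if (is.null(fallback_threshold)) {
    fallback_threshold <- max(phloxine_pre) / 2
  }
  if (nrow(cells) < 5) {
    cells$is_dead <- med > fallback_threshold
  } else if (diff(range(med)) < 1e-9) {
    cells$is_dead <- FALSE
  } else {
    th <- otsu_vector(med)
    lo <- med[med <= th]
    hi <- med[med > th]
    eps <- 1e-6
    if (length(hi) == 0 ||
      mean(hi) < min_separation * max(mean(lo), eps)) {
      cells$is_dead <- FALSE
    } else {
      cells$is_dead <- med > th
    }
  }
  seg$cells <- cells
  seg
}

#' Measure cell length and width from a mask
#'
#' Length is the maximal extent of the mask along its principal axis (PCA of
#' pixel coordinates) plus one pixel of pixel extent; width is twice the
#' maximal interior Euclidean distance-transform value. Both are converted
#' to micrometres and swapped if needed so that length >= width.
#'
#' @param mask Logical matrix (one connected cell).
#' @param pixel_size Pixel size, um/px.
#' @return Named numeric vector `length_um`, `width_um`.
#' @export
measure_cell <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 4) stop("mask smaller than 4 px")
  y <- idx[, 1]
  x <- idx[, 2]
  cx <- mean(x)
  cy <- mean(y)
  cv <- stats::cov(cbind(x - cx, y - cy))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- (x - cx) * ev[1] + (y - cy) * ev[2]
  length_px <- diff(range(proj)) + 1
  # pad the crop so the distance transform sees background on all sides
  i0 <- min(y)
  i1 <- max(y)
  j0 <- min(x)
  j1 <- max(x)
  crop <- matrix(0L, i1 - i0 + 3L, j1 - j0 + 3L)
  crop[cbind(y - i0 + 2L, x - j0 + 2L)] <- 1L
  dm <- EBImage::imageData(EBImage::distmap(crop))
  width_px <- 2 * max(dm)
  len <- length_px * pixel_size
  wid <- width_px * pixel_size
  if (wid > len) {
    tmp <- len
    len <- wid
    wid <- tmp
  }
  c(length_um = len, width_um = wid)
}
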