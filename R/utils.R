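# Internal geometry and numeric helpers shared across modules.
# Conventions: matrices are indexed [row, col] = [y, x], 0-based pixel
# coordinates with pixel (i, j) (0-based) covering [j, j+1] x [i, i+1] px and
# centred at (j + 0.5, i + 0.5); positions in micrometres convert to pixel
# units by division with the pixel size.

# Distance from points (px, py) to the segment (ax, ay)-(bx, by); vectorised
# over points.
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) {
    return(sqrt((px - ax)^2 + (py - ay)^2))
  }
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  qx <- ax + t * dx
  qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

# Closest point on a segment; scalar inputs.
closest_point_on_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) {
    return(c(ax, ay))
  }
  t <- min(1, max(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  c(ax + t * dx, ay + t * dy)
}

.orient <- function(ax, ay, bx, by, cx, cy) {
  sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
}

segments_intersect <- function(a, b, c, d) {
  o1 <- .orient(a[1], a[2], b[1], b[2], c[1], c[2])
  o2 <- .orient(a[1], a[2], b[1], b[2], d[1], d[2])
  o3 <- .orient(c[1], c[2], d[1], d[2], a[1], a[2])
  o4 <- .orient(c[1], c[2], d[1], d[2], b[1], b[2])
  (o1 != o2) && (o3 != o4)
}

# Minimum distance between two segments; for non-intersecting segments the
# minimum is attained at an endpoint of one of them.
segment_segment_dist <- function(a, b, c, d) {
  if (segments_intersect(a, b, c, d)) {
    return(0)
  }
  min(
    point_segment_dist(a[1], a[2], c[1], c[2], d[1], d[2]),
    point_segment_dist(b[1], b[2], c[1], c[2], d[1], d[2]),
    point_segment_dist(c[1], c[2], a[1], a[2], b[1], b[2]),
    point_segment_dist(d[1], d[2], a[1], a[2], b[1], b[2])
  )
}

# Axis endpoints (cap centres) of a spherocylinder cell given centre, angle,
# length L and width W (micrometres).
cell_axis_endpoints <- function(cx, cy, angle, length_um, width_um) {
  half <- (length_um - width_um) / 2
  ux <- cos(angle)
  uy <- sin(angle)
  c(
    ax = cx - half * ux, ay = cy - half * uy,
    bx = cx + half * ux, by = cy + half * uy
  )
}

point_in_cell <- function(px, py, cell, margin = 0) {
  e <- cell_axis_endpoints(cell$x_um, cell$y_um, cell$angle, cell$length_um, cell$width_um)
  point_segment_dist(px, py, e["ax"], e["ay"], e["bx"], e["by"]) <=
    cell$width_um / 2 - margin
}

# Specular fold of a point back into a spherocylinder (or a disc when the
# axis degenerates): the radial distance beyond the boundary is mirrored
# about it. Iterated because a large step can overshoot the far boundary.
reflect_into_spherocylinder <- function(px, py, ax, ay, bx, by, radius,
                                        max_iter = 25L) {
  for (i in seq_len(max_iter)) {
    d <- point_segment_dist(px, py, ax, ay, bx, by)
    if (d <= radius) {
      return(c(px, py))
    }
    q <- closest_point_on_segment(px, py, ax, ay, bx, by)
    s <- (2 * radius - d) / d
    px <- q[1] + (px - q[1]) * s
    py <- q[2] + (py - q[2]) * s
  }
  # pathological step size: clamp just inside
  q <- closest_point_on_segment(px, py, ax, ay, bx, by)
  d <- max(point_segment_dist(px, py, ax, ay, bx, by), 1e-12)
  c(q[1] + (px - q[1]) * 0.95 * radius / d, q[2] + (py - q[2]) * 0.95 * radius / d)
}

# Vectorised specular fold into a spherocylinder; a few whole-vector passes
# then a clamp for stragglers.
reflect_vec <- function(px, py, ax, ay, bx, by, radius) {
  for (pass in 1:4) {
    d <- point_segment_dist(px, py, ax, ay, bx, by)
    out <- d > radius
    if (!any(out)) {
      return(list(x = px, y = py))
    }
    dx <- bx - ax
    dy <- by - ay
    l2 <- dx * dx + dy * dy
    if (l2 == 0) {
      qx <- rep(ax, sum(out))
      qy <- rep(ay, sum(out))
    } else {
      t <- pmin(1, pmax(0, ((px[out] - ax) * dx + (py[out] - ay) * dy) / l2))
      qx <- ax + t * dx
      qy <- ay + t * dy
    }
    s <- (2 * radius - d[out]) / d[out]
    px[out] <- qx + (px[out] - qx) * s
    py[out] <- qy + (py[out] - qy) * s
  }
  d <- point_segment_dist(px, py, ax, ay, bx, by)
  out <- d > radius
  if (any(out)) {
    dx <- bx - ax
    dy <- by - ay
    l2 <- dx * dx + dy * dy
    if (l2 == 0) {
      qx <- rep(ax, sum(out))
      qy <- rep(ay, sum(out))
    } else {
      t <- pmin(1, pmax(0, ((px[out] - ax) * dx + (py[out] - ay) * dy) / l2))
      qx <- ax + t * dx
      qy <- ay + t * dy
    }
    sc <- 0.95 * radius / d[out]
    px[out] <- qx + (px[out] - qx) * sc
    py[out] <- qy + (py[out] - qy) * sc
  }
  list(x = px, y = py)
}

# Gaussian blur that tolerates small images: kernel capped to the image size,
# replicate boundary (no wrap-around into the opposite edge).
gauss_blur <- function(img, sigma) {
  stopifnot(sigma > 0)
  d <- dim(img)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- 2L * ((min(d) - 1L) %/% 2L) + 1L
  size <- min(size, cap)
  if (size < 3L) {
    return(img)
  }
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  out <- EBImage::filter2(img, k, boundary = "replicate")
  matrix(as.numeric(out), nrow = d[1], ncol = d[2])
}

# Two-class Otsu threshold on a numeric vector (used on per-cell intensity
# medians, where no image-based implementation applies).
otsu_vector <- function(v) {
  v <- sort(v[is.finite(v)])
  n <- length(v)
  if (n < 2 || diff(range(v)) == 0) {
    return(NA_real_)
  }
  cuts <- (v[-n] + v[-1]) / 2
  best <- -Inf
  best_cut <- NA_real_
  csum <- cumsum(v)
  total <- csum[n]
  for (k in seq_len(n - 1)) {
    n1 <- k
    n2 <- n - k
    m1 <- csum[k] / n1
    m2 <- (total - csum[k]) / n2
    bc <- n1 * n2 * (m1 - m2)^2
    if (bc > best) {
      best <- bc
      best_cut <- cuts[k]
    }
  }
  best_cut
}

# Add a Gaussian spot to an image in place-style (returns modified copy
# arguments in pixel units, pixel-centre convention).
add_gaussian_spot <- function(img, cx_px, cy_px, sigma_px, amplitude,
                              extent = 4) {
  h <- nrow(img)
  w <- ncol(img)
  r <- ceiling(extent * sigma_px)
  i0 <- max(1L, floor(cy_px - r) + 1L)
  i1 <- min(h, ceiling(cy_px + r) + 1L)
  j0 <- max(1L, floor(cx_px - r) + 1L)
  j1 <- min(w, ceiling(cx_px + r) + 1L)
  if (i0 > i1 || j0 > j1) {
    return(img)
  }
  yy <- (i0:i1) - 0.5 # pixel-centre y of rows (0-based centres)
  xx <- (j0:j1) - 0.5
  gy <- exp(-(yy - cy_px)^2 / (2 * sigma_px^2))
  gx <- exp(-(xx - cx_px)^2 / (2 * sigma_px^2))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amplitude * outer(gy, gx)
  img
}

# Deterministic sub-stream seed derivation from one global integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
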