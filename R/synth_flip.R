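#' FLIP scene configuration
#'
#' Configures a synthetic fluorescence-loss-in-photobleaching series on a
#' single spherocylindrical cell: frames acquired on a regular grid while a
#' small square near one cell pole is bleached periodically. Defaults follow
#' a standard FLIP protocol for fission yeast: a 1.12 x 1.12 um bleach square
#' near a pole, bleached every 5 s, with acquisition every 1 s for 100 s.
#'
#' @param cell_length,cell_width Cell geometry, um.
#' @param image_shape Image `(H, W)`, px.
#' @param with_control_cell Place a second, never-bleached cell in the same
#'   field; its centre region provides the acquisition-bleach control curve
#'   (the standard FLIP correction reference).
#' @param pixel_size Pixel size, um/px.
#' @param bleach_side Bleach square side, um.
#' @param bleach_offset Distance of the bleach-square centre from the cell
#'   pole towards the centre, um.
#' @param bleach_period Time between bleach pulses, s; must be an integer
#'   multiple of `acquisition_interval`.
#' @param acquisition_interval Frame interval, s.
#' @param duration Post-bleach observation window, s.
#' @param n_prebleach_frames Frames acquired before the first pulse.
#' @param bleach_efficiency Probability that an emitter dwelling in the
#'   bleach region during a full pulse is removed.
#' @param bleach_duration Bleach pulse dwell time, s (< `bleach_period`);
#'   the pulse is simulated as diffusion sub-steps with removal so that fast
#'   molecules sweeping through the spot during the dwell are bleached too.
#' @param mobile_fraction Fraction of emitters that diffuse; the rest are
#'   immobile and never enter the bleach region unless initialised there.
#' @param n_emitters Number of simulated point emitters.
#' @param emitter_brightness Counts contributed per emitter per pixel bin.
#' @param psf_sigma Rendering blur sigma, px (0 disables).
#' @param read_noise,poisson_scale Rendering noise, as in [scene_config()].
#' @param seed Integer seed.
#' @return A validated list of class `flip_scene_config`.
#' @export
flip_scene_config <- function(cell_length = 10, cell_width = 4,
                              image_shape = c(112L, 128L),
                              with_control_cell = TRUE,
                              pixel_size = 0.1,
                              bleach_side = 1.12,
                              bleach_offset = 1.2,
                              bleach_period = 5,
                              acquisition_interval = 1,
                              duration = 100,
                              n_prebleach_frames = 5L,
                              bleach_efficiency = 1,
                              bleach_duration = 1,
                              mobile_fraction = 1,
                              n_emitters = 5000L,
                              emitter_brightness = 1,
                              psf_sigma = 1,
                              read_noise = 0.2,
                              poisson_scale = 0.02,
                              seed = 1L) {
  cfg <- list(
    cell_length = cell_length, cell_width = cell_width,
    image_shape = as.integer(image_shape),
    with_control_cell = isTRUE(with_control_cell),
    pixel_size = pixel_size,
    bleach_side = bleach_side, bleach_offset = bleach_offset,
    bleach_period = bleach_period,
    acquisition_interval = acquisition_interval,
    duration = duration, n_prebleach_frames = as.integer(n_prebleach_frames),
    bleach_efficiency = bleach_efficiency,
    bleach_duration = bleach_duration,
    mobile_fraction = mobile_fraction,
    n_emitters = as.integer(n_emitters),
    emitter_brightness = emitter_brightness,
    psf_sigma = psf_sigma,
    read_noise = read_noise, poisson_scale = poisson_scale,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$cell_length >= cfg$cell_width, cfg$cell_width > 0,
    cfg$pixel_size > 0, cfg$bleach_side > 0,
    cfg$bleach_period > 0, cfg$acquisition_interval > 0,
    abs(cfg$bleach_period / cfg$acquisition_interval -
      round(cfg$bleach_period / cfg$acquisition_interval)) < 1e-9,
    cfg$duration > 0, cfg$n_prebleach_frames >= 1,
    cfg$bleach_efficiency >= 0, cfg$bleach_efficiency <= 1,
    cfg$bleach_duration > 0, cfg$bleach_duration < cfg$bleach_period,
    cfg$mobile_fraction >= 0, cfg$mobile_fraction <= 1,
    cfg$n_emitters > 0, cfg$bleach_side <= cfg$cell_width
  )
  structure(cfg, class = "flip_scene_config")
}

# Geometry helper: bleached cell (and optional unbleached control cell)
# with horizontal long axes, stacked vertically in the field.
flip_cell_geometry <- function(cfg) {
  h_um <- cfg$image_shape[1] * cfg$pixel_size
  w_um <- cfg$image_shape[2] * cfg$pixel_size
  dy <- if (cfg$with_control_cell) cfg$cell_width / 2 + 0.4 else 0
  cell <- list(
    x_um = w_um / 2, y_um = h_um / 2 - dy, angle = 0,
    length_um = cfg$cell_length, width_um = cfg$cell_width, cell = 1L
  )
  control_cell <- NULL
  control_region <- NULL
  if (cfg$with_control_cell) {
    control_cell <- list(
      x_um = w_um / 2, y_um = h_um / 2 + dy, angle = 0,
      length_um = cfg$cell_length, width_um = cfg$cell_width, cell = 2L
    )
    control_region <- list(
      x_um = control_cell$x_um, y_um = control_cell$y_um,
      side_um = cfg$bleach_side
    )
  }
  pole_left <- cell$x_um - cfg$cell_length / 2
  pole_right <- cell$x_um + cfg$cell_length / 2
  list(
    cell = cell, control_cell = control_cell,
    bleach_region = list(
      x_um = pole_left + cfg$bleach_offset, y_um = cell$y_um,
      side_um = cfg$bleach_side
    ),
    reference_region = list(
      x_um = pole_right - cfg$bleach_offset, y_um = cell$y_um,
      side_um = cfg$bleach_side
    ),
    control_region = control_region
  )
}

in_square <- function(x, y, region) {
  half <- region$side_um / 2
  abs(x - region$x_um) <= half & abs(y - region$y_um) <= half
}

#' Simulate a FLIP acquisition as diffusing point emitters
#'
#' Emitters start uniformly inside the cell; a `mobile_fraction` of them
#' diffuse with `diffusion_coeff` (specular reflection at the cell boundary),
#' the rest stay put. Between the pre-bleach frames and every
#' `bleach_period` thereafter a bleach pulse runs: during the pulse dwell the
#' mobile pool keeps diffusing in sub-steps and any emitter found inside the
#' bleach square is removed with the per-pulse efficiency spread over the
#' sub-steps. Frames are rendered by binning emitters into pixels, blurring
#' with a small PSF and adding noise.
#'
#' @param cfg A [flip_scene_config()].
#' @param diffusion_coeff Mobile-pool diffusion coefficient, um^2/s.
#' @param seed Integer seed (overrides `cfg$seed` when given).
#' @return List of class `flip_scene`: `stack` (single-channel
#'   `timelapse_stack`), `times` (s), `truth` data frame with the noiseless
#'   emitter counts in the bleach and reference regions per frame,
#'   `bleach_region`, `reference_region`, `prebleach_index`, `bleach_frames`.
#' @export
simulate_flip_stack <- function(cfg, diffusion_coeff = 10, seed = cfg$seed) {
  stopifnot(inherits(cfg, "flip_scene_config"), diffusion_coeff >= 0)
  set.seed(seed)
  geo <- flip_cell_geometry(cfg)
  cells <- list(geo$cell)
  if (!is.null(geo$control_cell)) cells[[2]] <- geo$control_cell
  ends <- lapply(cells, function(cl) {
    cell_axis_endpoints(cl$x_um, cl$y_um, cl$angle, cl$length_um, cl$width_um)
  })
  r <- cfg$cell_width / 2
  n_per <- cfg$n_emitters
  n <- n_per * length(cells)
  xs <- numeric(n)
  ys <- numeric(n)
  parent <- rep(seq_along(cells), each = n_per)
  half <- (cfg$cell_length - cfg$cell_width) / 2
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]
    e <- ends[[ci]]
    got <- 0L
    px <- numeric(n_per)
    py <- numeric(n_per)
    while (got < n_per) {
      m <- 2L * (n_per - got)
      cx <- runif(m, cl$x_um - half - r, cl$x_um + half + r)
      cy <- runif(m, cl$y_um - r, cl$y_um + r)
      keep <- point_segment_dist(cx, cy, e["ax"], e["ay"], e["bx"], e["by"]) <= r
      take <- min(sum(keep), n_per - got)
      if (take > 0) {
        px[got + seq_len(take)] <- cx[keep][seq_len(take)]
        py[got + seq_len(take)] <- cy[keep][seq_len(take)]
        got <- got + take
      }
    }
    xs[parent == ci] <- px
    ys[parent == ci] <- py
  }
  mobile <- rep(FALSE, n)
  for (ci in seq_along(cells)) {
    idx <- which(parent == ci)
    mobile[idx[seq_len(round(cfg$mobile_fraction * n_per))]] <- TRUE
  }
  alive <- rep(TRUE, n)

  dt <- cfg$acquisition_interval
  n_total <- cfg$n_prebleach_frames + as.integer(round(cfg$duration / dt))
  times <- (seq_len(n_total) - 1) * dt
  period_frames <- as.integer(round(cfg$bleach_period / dt))
  bleach_frames <- seq(cfg$n_prebleach_frames + 1L, n_total, by = period_frames)

  h <- cfg$image_shape[1]
  w <- cfg$image_shape[2]
  ps <- cfg$pixel_size
  arr <- array(0, dim = c(h, w, 1L, n_total))
  truth <- data.frame(
    frame = seq_len(n_total), t_s = times,
    bleach_count = NA_real_, reference_count = NA_real_,
    control_count = NA_real_, alive = NA_real_
  )

  diffuse <- function(xs, ys, idx, tau) {
    if (!any(idx) || diffusion_coeff == 0 || tau <= 0) {
      return(list(xs = xs, ys = ys))
    }
    sdv <- sqrt(2 * diffusion_coeff * tau)
    for (ci in seq_along(cells)) {
      ii <- which(idx & parent == ci)
      if (!length(ii)) next
      e <- ends[[ci]]
      nx <- xs[ii] + rnorm(length(ii), 0, sdv)
      ny <- ys[ii] + rnorm(length(ii), 0, sdv)
      p <- reflect_vec(nx, ny, e["ax"], e["ay"], e["bx"], e["by"], r)
      xs[ii] <- p$x
      ys[ii] <- p$y
    }
    list(xs = xs, ys = ys)
  }

  n_sub <- 10L
  p_sub <- 1 - (1 - cfg$bleach_efficiency)^(1 / n_sub)

  render <- function(xs, ys, alive) {
    img <- matrix(0, h, w)
    if (any(alive)) {
      jj <- pmin(pmax(floor(xs[alive] / ps), 0), w - 1) + 1L
      ii <- pmin(pmax(floor(ys[alive] / ps), 0), h - 1) + 1L
      counts <- table(factor(ii + (jj - 1L) * h, levels = seq_len(h * w)))
      img <- matrix(as.numeric(counts), h, w) * cfg$emitter_brightness
      if (cfg$psf_sigma > 0) img <- gauss_blur(img, cfg$psf_sigma)
    }
    if (cfg$read_noise > 0 || cfg$poisson_scale > 0) {
      sdmap <- sqrt(cfg$read_noise^2 + cfg$poisson_scale * pmax(img, 0))
      img <- pmax(img + rnorm(length(img), 0, as.numeric(sdmap)), 0)
    }
    img
  }

  for (f in seq_len(n_total)) {
    if (f > 1) {
      if (f %in% bleach_frames && cfg$bleach_efficiency > 0) {
        tau_sub <- cfg$bleach_duration / n_sub
        for (s in seq_len(n_sub)) {
          st <- diffuse(xs, ys, mobile & alive, tau_sub)
          xs <- st$xs
          ys <- st$ys
          inreg <- alive & in_square(xs, ys, geo$bleach_region)
          if (any(inreg)) {
            kill <- inreg & (runif(n) < p_sub)
            alive[kill] <- FALSE
          }
        }
        st <- diffuse(xs, ys, mobile & alive, max(dt - cfg$bleach_duration, 0))
        xs <- st$xs
        ys <- st$ys
      } else {
        st <- diffuse(xs, ys, mobile & alive, dt)
        xs <- st$xs
        ys <- st$ys
      }
    }
    truth$bleach_count[f] <- sum(alive & in_square(xs, ys, geo$bleach_region))
    truth$reference_count[f] <- sum(alive & in_square(xs, ys, geo$reference_region))
    truth$control_count[f] <- if (is.null(geo$control_region)) {
      NA_real_
    } else {
      sum(alive & in_square(xs, ys, geo$control_region))
    }
    truth$alive[f] <- sum(alive)
    arr[, , 1L, f] <- render(xs, ys, alive)
  }

  stack <- timelapse_stack(arr, ps, dt, channel_names = "flip")
  structure(
    list(
      stack = stack, times = times, truth = truth,
      bleach_region = geo$bleach_region,
      reference_region = geo$reference_region,
      control_region = geo$control_region,
      prebleach_index = cfg$n_prebleach_frames,
      bleach_frames = bleach_frames,
      config = cfg
    ),
    class = "flip_scene"
  )
}
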