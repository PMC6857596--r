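#' Synthetic scene configuration
#'
#' Defines a ground-truthed synthetic two-channel microscopy scene:
#' spherocylindrical (rod-shaped) cells on a dark background, bright
#' sub-resolution particles (lipid-droplet-like) in the droplet channel and a
#' vital-dye (phloxine-like) channel in which live cells show a dim outline
#' and dead cells fill brightly. Defaults mirror a spinning-disc acquisition
#' of starved fission yeast: 0.1 um/px, cells 7-14 um long and 3-4 um wide,
#' three frames 42 s apart for the PCC assay, and a multiplicative intensity
#' drift applied from frame 2 onward to the droplet channel.
#'
#' @param image_shape Integer `(H, W)` in pixels.
#' @param pixel_size Pixel size, um/px.
#' @param n_cells Number of cells to place.
#' @param cell_length_range,cell_width_range Uniform sampling ranges, um.
#' @param dead_fraction Fraction of cells flagged (and rendered) dead.
#' @param particles_per_cell Particles (droplets) per cell.
#' @param particle_sigma Rendered spot Gaussian sigma, px.
#' @param motion_model One of `"immobile"`, `"free"`, `"confined"`.
#' @param diffusion_coeff Diffusion coefficient, um^2/s.
#' @param confinement_radius Confinement radius for the confined model, um.
#' @param frame_interval Frame interval, s.
#' @param n_frames Number of frames.
#' @param intensity_drift Multiplicative droplet-channel factor applied to
#'   frames >= 2 (1 disables).
#' @param read_noise Gaussian read-noise standard deviation, counts.
#' @param poisson_scale Poisson-like variance scaling: the per-pixel noise
#'   variance is `read_noise^2 + poisson_scale * intensity`.
#' @param autofluor_density Mean autofluorescent distractor puncta per cell
#'   (Poisson), rendered static in the droplet channel.
#' @param particle_amplitude Spot peak amplitude, counts.
#' @param outline_intensity Live-cell rim intensity in the phloxine channel.
#' @param dead_fill_intensity Dead-cell interior fill intensity (default five
#'   times the outline).
#' @param background Constant background offset, counts.
#' @param seed Integer seed; the whole scene is a deterministic function of
#'   the configuration including this seed.
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(256L, 256L),
                         pixel_size = 0.1,
                         n_cells = 6L,
                         cell_length_range = c(7, 12),
                         cell_width_range = c(3, 4),
                         dead_fraction = 0,
                         particles_per_cell = 6L,
                         particle_sigma = 1.2,
                         motion_model = c("immobile", "free", "confined"),
                         diffusion_coeff = 0.01,
                         confinement_radius = 0.3,
                         frame_interval = 42,
                         n_frames = 3L,
                         intensity_drift = 1.15,
                         read_noise = 2,
                         poisson_scale = 0.05,
                         autofluor_density = 2,
                         particle_amplitude = 120,
                         outline_intensity = 30,
                         dead_fill_intensity = 150,
                         background = 5,
                         seed = 1L) {
  motion_model <- match.arg(motion_model)
  cfg <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_cells = as.integer(n_cells),
    cell_length_range = cell_length_range,
    cell_width_range = cell_width_range,
    dead_fraction = dead_fraction,
    particles_per_cell = as.integer(particles_per_cell),
    particle_sigma = particle_sigma, motion_model = motion_model,
    diffusion_coeff = diffusion_coeff,
    confinement_radius = confinement_radius,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    intensity_drift = intensity_drift, read_noise = read_noise,
    poisson_scale = poisson_scale, autofluor_density = autofluor_density,
    particle_amplitude = particle_amplitude,
    outline_intensity = outline_intensity,
    dead_fill_intensity = dead_fill_intensity,
    background = background, seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot(
    length(cfg$image_shape) == 2, all(cfg$image_shape >= 16),
    cfg$pixel_size > 0,
    cfg$n_cells >= 0,
    all(cfg$cell_length_range > 0), all(cfg$cell_width_range > 0),
    diff(cfg$cell_length_range) >= 0, diff(cfg$cell_width_range) >= 0,
    cfg$dead_fraction >= 0, cfg$dead_fraction <= 1,
    cfg$particles_per_cell >= 0,
    cfg$particle_sigma > 0,
    cfg$diffusion_coeff >= 0,
    cfg$frame_interval > 0, cfg$n_frames >= 1,
    cfg$intensity_drift > 0,
    cfg$read_noise >= 0, cfg$poisson_scale >= 0,
    cfg$autofluor_density >= 0,
    cfg$seed == round(cfg$seed)
  )
  if (cfg$motion_model == "confined") {
    stopifnot(cfg$confinement_radius > 0)
  }
  invisible(cfg)
}

# Rejection-sample non-overlapping spherocylinder geometries fully inside the
# field of view. Sampled widths never exceed lengths (enforced by swap).
sample_cell_geometries <- function(cfg) {
  h_um <- cfg$image_shape[1] * cfg$pixel_size
  w_um <- cfg$image_shape[2] * cfg$pixel_size
  clearance <- 0.3
  cells <- vector("list", cfg$n_cells)
  ends <- list()
  for (i in seq_len(cfg$n_cells)) {
    placed <- FALSE
    for (attempt in seq_len(2000L)) {
      L <- runif(1, cfg$cell_length_range[1], cfg$cell_length_range[2])
      W <- runif(1, cfg$cell_width_range[1], cfg$cell_width_range[2])
      if (W > L) {
        tmp <- L
        L <- W
        W <- tmp
      }
      ang <- runif(1, 0, pi)
      m <- L / 2 + 2 * cfg$pixel_size
      if (w_um <= 2 * m || h_um <= 2 * m) next
      cx <- runif(1, m, w_um - m)
      cy <- runif(1, m, h_um - m)
      e <- cell_axis_endpoints(cx, cy, ang, L, W)
      ok <- TRUE
      for (j in seq_along(ends)) {
        dd <- segment_segment_dist(
          c(e["ax"], e["ay"]), c(e["bx"], e["by"]),
          ends[[j]]$a, ends[[j]]$b
        )
        if (dd < (W + ends[[j]]$w) / 2 + clearance) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        cells[[i]] <- data.frame(
          cell = i, x_um = cx, y_um = cy, angle = ang,
          length_um = L, width_um = W
        )
        ends[[length(ends) + 1]] <- list(
          a = c(e["ax"], e["ay"]), b = c(e["bx"], e["by"]), w = W
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", cfg$n_cells, " non-overlapping cells; ",
        "reduce n_cells or enlarge image_shape",
        call. = FALSE
      )
    }
  }
  do.call(rbind, cells)
}

# Uniform point inside a spherocylinder, kept `margin` um from the boundary.
sample_point_in_cell <- function(cell, margin = 0.25) {
  e <- cell_axis_endpoints(
    cell$x_um, cell$y_um, cell$angle,
    cell$length_um, cell$width_um
  )
  r <- cell$width_um / 2 - margin
  stopifnot(r > 0)
  half <- (cell$length_um - cell$width_um) / 2
  for (i in seq_len(1000L)) {
    u <- runif(1, -(half + r), half + r)
    v <- runif(1, -r, r)
    px <- cell$x_um + u * cos(cell$angle) - v * sin(cell$angle)
    py <- cell$y_um + u * sin(cell$angle) + v * cos(cell$angle)
    if (point_segment_dist(px, py, e["ax"], e["ay"], e["bx"], e["by"]) <= r) {
      return(c(px, py))
    }
  }
  c(cell$x_um, cell$y_um)
}

#' Simulate particle trajectories inside spherocylinder cells
#'
#' Motion models: `"free"` draws 2-D Brownian steps with per-axis variance
#' `2 * D * dt` and folds steps specularly back at the cell boundary;
#' `"confined"` additionally folds steps at a disc of `confinement_radius`
#' about each particle's start position; `"immobile"` keeps positions
#' constant. Deterministic for a fixed seed.
#'
#' @param cells Data frame of cell geometries (`cell`, `x_um`, `y_um`,
#'   `angle`, `length_um`, `width_um`), e.g. from [simulate_scene()].
#' @param particles_per_cell Particles per cell.
#' @param motion_model `"immobile"`, `"free"` or `"confined"`.
#' @param n_frames Number of frames.
#' @param frame_interval Frame interval, s (positive).
#' @param diffusion_coeff Diffusion coefficient, um^2/s (non-negative).
#' @param confinement_radius Confinement radius, um (confined model only).
#' @param seed Integer seed.
#' @return Data frame `particle, cell, frame, x_um, y_um` (positions in um).
#' @export
simulate_particles <- function(cells, particles_per_cell,
                               motion_model = c("immobile", "free", "confined"),
                               n_frames, frame_interval,
                               diffusion_coeff = 0,
                               confinement_radius = NULL,
                               seed = 1L) {
  motion_model <- match.arg(motion_model)
  stopifnot(frame_interval > 0, diffusion_coeff >= 0, n_frames >= 1)
  if (motion_model == "confined") {
    stopifnot(!is.null(confinement_radius), confinement_radius > 0)
  }
  set.seed(seed)
  step_sd <- sqrt(2 * diffusion_coeff * frame_interval)
  out <- vector("list", nrow(cells) * particles_per_cell)
  pid <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    e <- cell_axis_endpoints(
      cell$x_um, cell$y_um, cell$angle,
      cell$length_um, cell$width_um
    )
    r <- cell$width_um / 2
    for (k in seq_len(particles_per_cell)) {
      pid <- pid + 1L
      p0 <- sample_point_in_cell(cell, margin = min(0.25, r / 3))
      xs <- numeric(n_frames)
      ys <- numeric(n_frames)
      xs[1] <- p0[1]
      ys[1] <- p0[2]
      if (motion_model != "immobile" && step_sd > 0 && n_frames > 1) {
        dx <- rnorm(n_frames - 1, 0, step_sd)
        dy <- rnorm(n_frames - 1, 0, step_sd)
        for (f in 2:n_frames) {
          px <- xs[f - 1] + dx[f - 1]
          py <- ys[f - 1] + dy[f - 1]
          if (motion_model == "confined") {
            p <- reflect_into_spherocylinder(
              px, py, p0[1], p0[2], p0[1], p0[2],
              confinement_radius
            )
            px <- p[1]
            py <- p[2]
          }
          p <- reflect_into_spherocylinder(
            px, py, e["ax"], e["ay"], e["bx"], e["by"], r
          )
          xs[f] <- p[1]
          ys[f] <- p[2]
        }
      } else {
        xs[] <- p0[1]
        ys[] <- p0[2]
      }
      out[[pid]] <- data.frame(
        particle_id = pid, cell = cell$cell, frame = seq_len(n_frames),
        x_um = xs, y_um = ys
      )
    }
  }
  if (pid == 0L) {
    return(data.frame(
      particle_id = integer(), cell = integer(), frame = integer(),
      x_um = numeric(), y_um = numeric()
    ))
  }
  do.call(rbind, out)
}

#' Add localisation noise to trajectories
#'
#' Adds independent Gaussian noise of standard deviation `sigma_loc` (um) to
#' every observed position, emulating the static localisation error of a
#' detector. For immobile particles the resulting ensemble MSD plateaus at
#' `4 * sigma_loc^2` independent of lag.
#'
#' @param trajectories Data frame from [simulate_particles()].
#' @param sigma_loc Localisation error standard deviation, um.
#' @param seed Integer seed.
#' @return The trajectories with perturbed `x_um`, `y_um`.
#' @export
add_localisation_noise <- function(trajectories, sigma_loc, seed = 1L) {
  stopifnot(sigma_loc >= 0)
  set.seed(seed)
  n <- nrow(trajectories)
  trajectories$x_um <- trajectories$x_um + rnorm(n, 0, sigma_loc)
  trajectories$y_um <- trajectories$y_um + rnorm(n, 0, sigma_loc)
  trajectories
}

# Render the phloxine-like channel for one frame: live cells as a dim closed
# rim, dead cells brightly filled; rim thickness ~0.25 um (>=2 px so that the
# outline is closed for hole filling).
render_phloxine <- function(cells, dead, cfg) {
  h <- cfg$image_shape[1]
  w <- cfg$image_shape[2]
  img <- matrix(cfg$background, h, w)
  ps <- cfg$pixel_size
  rim_um <- max(0.25, 2 * ps)
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    e <- cell_axis_endpoints(
      cell$x_um, cell$y_um, cell$angle,
      cell$length_um, cell$width_um
    ) / ps
    r_px <- cell$width_um / 2 / ps
    pad <- ceiling(r_px) + 2
    j0 <- max(1L, floor(min(e["ax"], e["bx"]) - pad) + 1L)
    j1 <- min(w, ceiling(max(e["ax"], e["bx"]) + pad))
    i0 <- max(1L, floor(min(e["ay"], e["by"]) - pad) + 1L)
    i1 <- min(h, ceiling(max(e["ay"], e["by"]) + pad))
    xx <- (j0:j1) - 0.5
    yy <- (i0:i1) - 0.5
    g <- expand.grid(y = yy, x = xx)
    d <- point_segment_dist(g$x, g$y, e["ax"], e["ay"], e["bx"], e["by"])
    d <- matrix(d, nrow = length(yy))
    rim <- d <= r_px & d > r_px - rim_um / ps
    sub <- img[i0:i1, j0:j1]
    if (dead[i]) {
      fill <- d <= r_px
      sub[fill] <- cfg$background + cfg$dead_fill_intensity
      sub[rim] <- cfg$background + cfg$dead_fill_intensity
    } else {
      sub[rim] <- cfg$background + cfg$outline_intensity
    }
    img[i0:i1, j0:j1] <- sub
  }
  img
}

apply_noise <- function(img, cfg) {
  if (cfg$read_noise == 0 && cfg$poisson_scale == 0) {
    return(img)
  }
  sdmap <- sqrt(cfg$read_noise^2 + cfg$poisson_scale * pmax(img, 0))
  pmax(img + rnorm(length(img), 0, as.numeric(sdmap)), 0)
}

#' Render a ground-truth scene into a two-channel time-lapse stack
#'
#' Channel 1 (droplet) renders each particle as a Gaussian spot of
#' `particle_sigma` plus static autofluorescent distractor puncta; frames
#' >= 2 are scaled by `intensity_drift` before noise, emulating the gradual
#' dye-signal increase between the first and second acquisition. Channel 2
#' (phloxine) renders live cells as a dim outline and dead cells brightly
#' filled. Noise is applied last.
#'
#' @param truth Ground truth list from [simulate_scene()] (fields `cells`,
#'   `dead`, `trajectories`, `autofluor`).
#' @param cfg A [scene_config()].
#' @param noise_seed Integer seed for the rendering noise stream.
#' @return A `timelapse_stack` with channels `droplet`, `phloxine`.
#' @export
render_timelapse <- function(truth, cfg, noise_seed = derive_seed(cfg$seed, 1)) {
  h <- cfg$image_shape[1]
  w <- cfg$image_shape[2]
  ps <- cfg$pixel_size
  nt <- cfg$n_frames
  arr <- array(0, dim = c(h, w, 2L, nt))
  phlox <- render_phloxine(truth$cells, truth$dead, cfg)
  traj <- truth$trajectories
  af <- truth$autofluor
  max_px <- c(w, h)
  set.seed(noise_seed)
  for (t in seq_len(nt)) {
    img <- matrix(cfg$background, h, w)
    if (!is.null(af) && nrow(af) > 0) {
      for (k in seq_len(nrow(af))) {
        img <- add_gaussian_spot(
          img, af$x_um[k] / ps, af$y_um[k] / ps,
          cfg$particle_sigma, af$amplitude[k]
        )
      }
    }
    if (nrow(traj) > 0) {
      ft <- traj[traj$frame == t, ]
      for (k in seq_len(nrow(ft))) {
        cx <- ft$x_um[k] / ps
        cy <- ft$y_um[k] / ps
        if (cx < 0 || cx > max_px[1] || cy < 0 || cy > max_px[2]) {
          stop("particle outside image bounds after um->px conversion")
        }
        img <- add_gaussian_spot(
          img, cx, cy, cfg$particle_sigma,
          cfg$particle_amplitude
        )
      }
    }
    if (t >= 2) img <- img * cfg$intensity_drift
    arr[, , 1L, t] <- apply_noise(img, cfg)
    arr[, , 2L, t] <- apply_noise(phlox, cfg)
  }
  timelapse_stack(arr, ps, cfg$frame_interval,
    channel_names = c("droplet", "phloxine")
  )
}

#' Simulate a complete ground-truthed scene
#'
#' Samples cell geometries and dead flags, simulates particle trajectories
#' under the configured motion model, and renders the two-channel stack. All
#' randomness derives deterministically from `cfg$seed`.
#'
#' @param cfg A [scene_config()].
#' @return List of class `cf_scene` with elements `stack`
#'   (a `timelapse_stack`), `truth` (list: `cells` data frame with `dead`
#'   flag, `dead` logical vector, `trajectories`, `autofluor`) and `config`.
#' @export
simulate_scene <- function(cfg) {
  validate_scene_config(cfg)
  set.seed(cfg$seed)
  cells <- sample_cell_geometries(cfg)
  n_dead <- round(cfg$dead_fraction * cfg$n_cells)
  dead <- rep(FALSE, cfg$n_cells)
  if (n_dead > 0) dead[sample(cfg$n_cells, n_dead)] <- TRUE
  af <- NULL
  if (cfg$autofluor_density > 0 && cfg$n_cells > 0) {
    rows <- list()
    for (i in seq_len(nrow(cells))) {
      n_af <- rpois(1, cfg$autofluor_density)
      if (n_af > 0) {
        for (k in seq_len(n_af)) {
          p <- sample_point_in_cell(cells[i, ], margin = 0.2)
          rows[[length(rows) + 1]] <- data.frame(
            cell = i, x_um = p[1], y_um = p[2],
            amplitude = cfg$particle_amplitude * runif(1, 0.1, 0.3)
          )
        }
      }
    }
    af <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  traj <- simulate_particles(
    cells, cfg$particles_per_cell, cfg$motion_model,
    cfg$n_frames, cfg$frame_interval, cfg$diffusion_coeff,
    cfg$confinement_radius,
    seed = derive_seed(cfg$seed, 2)
  )
  cells$dead <- dead
  truth <- list(
    cells = cells, dead = dead, trajectories = traj, autofluor = af,
    diffusion_coeff = cfg$diffusion_coeff
  )
  stack <- render_timelapse(truth, cfg)
  structure(list(stack = stack, truth = truth, config = cfg),
    class = "cf_scene"
  )
}

#' Write scene ground truth as plain-text tables
#'
#' Writes `<prefix>_cells.csv` (cell geometries and dead flags) and
#' `<prefix>_tracks.csv` (frame, particle_id, x_um, y_um).
#'
#' @param scene A `cf_scene` from [simulate_scene()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_scene_truth <- function(scene, prefix) {
  cells_path <- paste0(prefix, "_cells.csv")
  tracks_path <- paste0(prefix, "_tracks.csv")
  write.csv(scene$truth$cells, cells_path, row.names = FALSE)
  tr <- scene$truth$trajectories
  write.csv(
    data.frame(
      frame = tr$frame, particle_id = tr$particle_id,
      x_um = tr$x_um, y_um = tr$y_um, cell = tr$cell
    ),
    tracks_path,
    row.names = FALSE
  )
  invisible(c(cells_path, tracks_path))
}
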