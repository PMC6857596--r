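# Synthetic scene generator: determinism, motion statistics, rendering.

test_that("fixed seed gives bit-identical scenes and particle counts match", {
  cfg <- small_scene_config(seed = 9L)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$stack$data, s2$stack$data)
  expect_identical(s1$truth$trajectories, s2$truth$trajectories)
  expect_equal(
    length(unique(s1$truth$trajectories$particle_id)),
    cfg$n_cells * cfg$particles_per_cell
  )
  # every particle inside its parent cell at every frame
  tr <- s1$truth$trajectories
  for (ci in seq_len(nrow(s1$truth$cells))) {
    cell <- s1$truth$cells[ci, ]
    sub <- tr[tr$cell == cell$cell, ]
    expect_true(all(
      cytofreeze:::point_in_cell(sub$x_um, sub$y_um, cell, margin = -1e-9)
    ))
  }
})

test_that("immobile and zero-D trajectories have zero displacement", {
  cells <- arena_cell()
  for (mm in c("immobile", "free")) {
    tr <- simulate_particles(cells, 5L, mm,
      n_frames = 100L,
      frame_interval = 0.25, diffusion_coeff = 0, seed = 3L
    )
    disp <- tapply(tr$x_um, tr$particle_id, function(v) diff(range(v))) +
      tapply(tr$y_um, tr$particle_id, function(v) diff(range(v)))
    expect_true(all(disp == 0))
  }
})

test_that("free-diffusion step variance matches 2 D dt", {
  d <- 0.01
  dt <- 0.25
  tr <- simulate_particles(arena_cell(), 200L, "free",
    n_frames = 51L,
    frame_interval = dt, diffusion_coeff = d, seed = 11L
  )
  steps_x <- unlist(lapply(split(tr$x_um, tr$particle_id), diff))
  steps_y <- unlist(lapply(split(tr$y_um, tr$particle_id), diff))
  expect_equal(var(steps_x), 2 * d * dt, tolerance = 0.05)
  expect_equal(var(steps_y), 2 * d * dt, tolerance = 0.05)
})

test_that("confined motion never leaves the confinement disc", {
  rad <- 0.3
  tr <- simulate_particles(arena_cell(), 20L, "confined",
    n_frames = 300L, frame_interval = 0.25,
    diffusion_coeff = 0.05, confinement_radius = rad, seed = 5L
  )
  for (sub in split(tr, tr$particle_id)) {
    dist0 <- sqrt((sub$x_um - sub$x_um[1])^2 + (sub$y_um - sub$y_um[1])^2)
    expect_true(all(dist0 <= rad + 1e-9))
  }
})

test_that("invalid motion parameters error", {
  expect_error(simulate_particles(arena_cell(), 1L, "free",
    n_frames = 5L, frame_interval = -1, diffusion_coeff = 0.01
  ))
  expect_error(simulate_particles(arena_cell(), 1L, "confined",
    n_frames = 5L, frame_interval = 1, diffusion_coeff = 0.01,
    confinement_radius = 0
  ))
})

test_that("rendering places spots at the true positions", {
  cfg <- small_scene_config(
    n_cells = 1L, particles_per_cell = 1L,
    autofluor_density = 0, read_noise = 0, poisson_scale = 0, seed = 21L
  )
  sc <- simulate_scene(cfg)
  f <- get_frame(sc$stack, 1, "droplet")
  pos <- sc$truth$trajectories[sc$truth$trajectories$frame == 1, ]
  idx <- which(f == max(f), arr.ind = TRUE)[1, ]
  # argmax pixel centre within 1 px of the true position
  expect_lt(abs((idx[2] - 0.5) - pos$x_um / cfg$pixel_size), 1)
  expect_lt(abs((idx[1] - 0.5) - pos$y_um / cfg$pixel_size), 1)
})

test_that("static noiseless scenes are conserved and drift-consistent", {
  cfg <- small_scene_config(
    read_noise = 0, poisson_scale = 0,
    intensity_drift = 1, seed = 13L
  )
  sc <- simulate_scene(cfg)
  # all droplet frames bit-identical; total intensity conserved
  expect_identical(sc$stack$data[, , 1, 1], sc$stack$data[, , 1, 2])
  expect_identical(sc$stack$data[, , 1, 1], sc$stack$data[, , 1, 3])
  # with drift: frame 2 = drift * frame 1, frames 2 and 3 identical
  cfg2 <- small_scene_config(
    read_noise = 0, poisson_scale = 0,
    intensity_drift = 1.15, seed = 13L
  )
  sc2 <- simulate_scene(cfg2)
  expect_equal(sc2$stack$data[, , 1, 2], 1.15 * sc2$stack$data[, , 1, 1],
    tolerance = 1e-12
  )
  expect_identical(sc2$stack$data[, , 1, 2], sc2$stack$data[, , 1, 3])
})

test_that("phloxine channel renders dead cells filled and live cells hollow", {
  cfg <- small_scene_config(
    dead_fraction = 0, read_noise = 0,
    poisson_scale = 0, seed = 17L
  )
  sc <- simulate_scene(cfg)
  ph <- get_frame(sc$stack, 1, "phloxine")
  # no pixel above outline intensity when nothing is dead
  expect_lte(max(ph), cfg$background + cfg$outline_intensity)
  cfg2 <- small_scene_config(
    dead_fraction = 0.5, read_noise = 0,
    poisson_scale = 0, seed = 17L
  )
  sc2 <- simulate_scene(cfg2)
  ph2 <- get_frame(sc2$stack, 1, "phloxine")
  expect_gt(max(ph2), cfg2$background + cfg2$outline_intensity)
})

test_that("stack TIFF round trip preserves metadata and values", {
  cfg <- small_scene_config(seed = 31L)
  sc <- simulate_scene(cfg)
  tf <- tempfile(fileext = ".tif")
  write_stack_tiff(sc$stack, tf)
  back <- read_stack_tiff(tf)
  expect_equal(back$pixel_size, sc$stack$pixel_size)
  expect_equal(back$frame_interval, sc$stack$frame_interval)
  expect_equal(back$channel_names, sc$stack$channel_names)
  # 32-bit float storage: relative error bounded
  expect_equal(back$data, sc$stack$data, tolerance = 1e-6)
})
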