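# Particle detection, trajectory linking, retention filters and MSD.

test_that("rendered spots are detected within half a pixel", {
  set.seed(8)
  img <- matrix(3, 128, 128)
  truth <- data.frame(
    x = runif(15, 12, 116), y = runif(15, 12, 116)
  )
  # enforce separation so spots do not overlap
  repeat {
    d <- as.matrix(dist(truth))
    diag(d) <- Inf
    bad <- which(apply(d, 1, min) < 10)
    if (!length(bad)) break
    truth$x[bad] <- runif(length(bad), 12, 116)
    truth$y[bad] <- runif(length(bad), 12, 116)
  }
  for (k in seq_len(15)) {
    img <- cytofreeze:::add_gaussian_spot(img, truth$x[k], truth$y[k], 1.3, 100)
  }
  img <- img + matrix(rnorm(128 * 128, 0, 2), 128, 128)
  det <- detect_particles(img, radius_px = 4)
  expect_equal(nrow(det), 15L)
  for (k in seq_len(15)) {
    d <- sqrt((det$x_px - truth$x[k])^2 + (det$y_px - truth$y[k])^2)
    expect_lt(min(d), 0.5)
  }
})

test_that("blank noisy frames yield no detections at the default cutoff", {
  for (s in 1:3) {
    set.seed(400 + s)
    img <- matrix(3, 96, 96) + matrix(rnorm(96 * 96, 0, 2), 96, 96)
    expect_equal(nrow(detect_particles(img, radius_px = 4)), 0L)
  }
})

test_that("a spot at a pixel centre is localised there", {
  img <- matrix(0, 64, 64)
  img <- cytofreeze:::add_gaussian_spot(img, 30.5, 40.5, 1.3, 100)
  det <- detect_particles(img, radius_px = 4, quality_cutoff = 1)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_px - 30.5), 0.1)
  expect_lt(abs(det$y_px - 40.5), 0.1)
})

test_that("immobile particles link into full-length trajectories", {
  det <- lapply(1:300, function(f) {
    data.frame(x_px = c(20, 30), y_px = c(20, 20))
  })
  tr <- link_tracks(det, max_displacement_px = 2, gap_max = 0)
  expect_equal(length(unique(tr$particle_id)), 2L)
  expect_equal(as.integer(table(tr$particle_id)), c(300L, 300L))
})

test_that("crossing paths with large separation keep their identities", {
  # two particles approach and pass; per-step displacement 1 px but the
  # inter-particle distance always exceeds the link radius
  frames <- 1:21
  xa <- 10 + frames
  xb <- 42 - frames
  det <- lapply(seq_along(frames), function(i) {
    data.frame(x_px = c(xa[i], xb[i]), y_px = c(10, 14))
  })
  tr <- link_tracks(det, max_displacement_px = 1.5, gap_max = 0)
  expect_equal(length(unique(tr$particle_id)), 2L)
  t1 <- tr[tr$particle_id == 1, ]
  expect_equal(t1$x_um, xa)
  expect_equal(t1$y_um, rep(10, 21))
})

test_that("gaps up to gap_max are bridged into one trajectory", {
  det <- lapply(1:10, function(f) {
    if (f %in% c(5, 6)) {
      data.frame(x_px = numeric(), y_px = numeric())
    } else {
      data.frame(x_px = 15, y_px = 15)
    }
  })
  tr <- link_tracks(det, max_displacement_px = 2, gap_max = 3)
  expect_equal(length(unique(tr$particle_id)), 1L)
  expect_equal(nrow(tr), 8L)
  # gap beyond gap_max splits the track
  tr2 <- link_tracks(det, max_displacement_px = 2, gap_max = 1)
  expect_equal(length(unique(tr2$particle_id)), 2L)
})

test_that("track-retention thresholds keep exactly the right subsets", {
  mk <- function(id, n) make_traj(id, seq_len(n), rep(0, n), rep(0, n))
  tr <- rbind(mk(1, 150), mk(2, 161), mk(3, 300))
  kept <- filter_tracks(tr, min_frames = 160)
  expect_equal(sort(unique(kept$particle_id)), c(2, 3))
  # 100-frame movies: strictly more than 95 frames
  tr2 <- rbind(mk(1, 95), mk(2, 96), mk(3, 100))
  kept2 <- filter_tracks(tr2, min_frames = 95)
  expect_equal(sort(unique(kept2$particle_id)), c(2, 3))
  # all short -> empty; min 0 -> identity; idempotent
  expect_equal(nrow(filter_tracks(tr, min_frames = 400)), 0L)
  expect_equal(filter_tracks(tr, 0)$particle_id, tr$particle_id)
  expect_equal(filter_tracks(kept, 160), kept)
})

test_that("time-averaged MSD matches hand computation on uniform motion", {
  tr <- make_traj(1L, 1:4, c(0, 1, 2, 3), rep(0, 4))
  curve <- time_avg_msd(tr, lag_max = 3, frame_interval = 1)
  expect_equal(curve$msd_um2, c(1, 4, 9), tolerance = 1e-9)
  expect_equal(curve$n_pairs, c(3L, 2L, 1L))
  # static trajectory -> all-zero MSD
  st <- make_traj(2L, 1:10, rep(1, 10), rep(2, 10))
  expect_true(all(time_avg_msd(st, lag_max = 5)$msd_um2 == 0))
  expect_error(time_avg_msd(tr, lag_max = 4))
})

test_that("ensemble MSD matches the free-diffusion closed form", {
  d <- 0.01
  dt <- 0.25
  tr <- simulate_particles(arena_cell(), 1000L, "free",
    n_frames = 40L, frame_interval = dt, diffusion_coeff = d, seed = 12L
  )
  curves <- time_avg_msd(tr, lag_max = 10, frame_interval = dt)
  ens <- ensemble_msd(curves)
  expect_equal(ens$ensemble$msd_um2, 4 * d * ens$ensemble$lag_s,
    tolerance = 0.1
  )
})

test_that("ensemble averaging and histograms conserve particles", {
  c1 <- time_avg_msd(make_traj(1L, 1:5, c(0, 1, 2, 3, 4), rep(0, 5)), 3, 1)
  ens1 <- ensemble_msd(c1)
  expect_equal(ens1$ensemble$msd_um2, c1$msd_um2)
  # two curves -> mean
  c2 <- time_avg_msd(make_traj(2L, 1:5, c(0, 2, 4, 6, 8), rep(0, 5)), 3, 1)
  both <- rbind(c1, c2)
  attr(both, "frame_interval") <- 1
  ens2 <- ensemble_msd(both)
  expect_equal(ens2$ensemble$msd_um2, (c1$msd_um2 + c2$msd_um2) / 2)
  # histogram column sums equal particle counts at every lag
  expect_true(all(colSums(ens2$hist) == 2L))
  # inconsistent lag grids error
  c3 <- time_avg_msd(make_traj(3L, 1:3, c(0, 1, 2), rep(0, 3)), 2, 1)
  bad <- rbind(c1, c3)
  expect_error(ensemble_msd(bad))
})

test_that("tracking a rendered immobile movie recovers the particles", {
  cfg <- small_scene_config(
    n_cells = 2L, particles_per_cell = 3L,
    n_frames = 20L, frame_interval = 0.25,
    autofluor_density = 0, seed = 55L
  )
  sc <- simulate_scene(cfg)
  tr <- track_movie(sc$stack, channel = "droplet", max_displacement_px = 3)
  counts <- table(tr$particle_id)
  expect_equal(sum(counts == 20L), 6L)
})
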