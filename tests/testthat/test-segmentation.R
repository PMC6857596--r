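# Cell segmentation, dead-cell classification and morphometric measurement.

prep_phloxine <- function(scene) {
  log_background_subtract(get_frame(scene$stack, 1, "phloxine"), 20)
}

test_that("non-touching cells are segmented with ground-truth centres inside", {
  cfg <- small_scene_config(n_cells = 4L, seed = 101L)
  sc <- simulate_scene(cfg)
  pre <- prep_phloxine(sc)
  seg <- segment_cells(pre, cfg$pixel_size)
  expect_equal(nrow(seg$cells), cfg$n_cells)
  # each true centre lies inside exactly one mask
  hits <- integer(nrow(sc$truth$cells))
  for (i in seq_len(nrow(sc$truth$cells))) {
    ci <- floor(sc$truth$cells$y_um[i] / cfg$pixel_size) + 1
    cj <- floor(sc$truth$cells$x_um[i] / cfg$pixel_size) + 1
    hits[i] <- seg$labels[ci, cj]
  }
  expect_true(all(hits > 0))
  expect_equal(length(unique(hits)), cfg$n_cells)
})

test_that("segmentation achieves >= 95% pixel agreement with ground truth", {
  cfg <- small_scene_config(n_cells = 4L, seed = 103L)
  sc <- simulate_scene(cfg)
  pre <- prep_phloxine(sc)
  seg <- segment_cells(pre, cfg$pixel_size)
  # ground-truth label map from the generator geometry
  h <- cfg$image_shape[1]
  w <- cfg$image_shape[2]
  gt <- matrix(0L, h, w)
  xs <- (col(gt) - 0.5) * cfg$pixel_size
  ys <- (row(gt) - 0.5) * cfg$pixel_size
  for (i in seq_len(nrow(sc$truth$cells))) {
    cell <- sc$truth$cells[i, ]
    e <- cytofreeze:::cell_axis_endpoints(
      cell$x_um, cell$y_um, cell$angle, cell$length_um, cell$width_um
    )
    inside <- cytofreeze:::point_segment_dist(
      xs, ys, e["ax"], e["ay"], e["bx"], e["by"]
    ) <= cell$width_um / 2
    gt[inside] <- i
  }
  # map segmentation labels to ground-truth labels by majority vote
  agree <- 0
  total <- sum(gt > 0)
  for (i in seq_len(nrow(sc$truth$cells))) {
    seg_ids <- seg$labels[gt == i]
    seg_ids <- seg_ids[seg_ids > 0]
    if (!length(seg_ids)) next
    maj <- as.integer(names(which.max(table(seg_ids))))
    agree <- agree + sum(gt == i & seg$labels == maj)
  }
  expect_gte(agree / total, 0.95)
})

test_that("touching cells are separated by their interior seeds", {
  # hand-built geometry: two parallel cells sharing a rim
  cfg <- small_scene_config(n_cells = 0L, read_noise = 1, seed = 105L)
  cells <- data.frame(
    cell = 1:2,
    x_um = c(9.6, 9.6), y_um = c(8.0, 11.4), angle = c(0, 0),
    length_um = c(9, 9), width_um = c(3.4, 3.4)
  )
  truth <- list(
    cells = cells, dead = c(FALSE, FALSE),
    trajectories = data.frame(
      particle_id = integer(), cell = integer(), frame = integer(),
      x_um = numeric(), y_um = numeric()
    ),
    autofluor = NULL
  )
  stack <- render_timelapse(truth, cfg)
  pre <- log_background_subtract(get_frame(stack, 1, "phloxine"), 20)
  seg <- segment_cells(pre, cfg$pixel_size)
  expect_equal(nrow(seg$cells), 2L)
  lab1 <- seg$labels[cells$y_um[1] / cfg$pixel_size, cells$x_um[1] / cfg$pixel_size]
  lab2 <- seg$labels[cells$y_um[2] / cfg$pixel_size, cells$x_um[2] / cfg$pixel_size]
  expect_true(lab1 > 0 && lab2 > 0 && lab1 != lab2)
})

test_that("blank images yield zero labels without error", {
  seg <- segment_cells(matrix(0, 64, 64), 0.1)
  expect_equal(nrow(seg$cells), 0L)
  expect_true(all(seg$labels == 0))
})

test_that("dead cells are flagged exactly and robustly", {
  cfg <- small_scene_config(
    image_shape = c(256L, 256L), n_cells = 8L,
    dead_fraction = 0.25, seed = 11L
  )
  sc <- simulate_scene(cfg)
  pre <- prep_phloxine(sc)
  seg <- classify_dead(segment_cells(pre, cfg$pixel_size), pre, cfg$pixel_size)
  # match each segmented cell to the nearest true cell
  truth_dead <- logical(nrow(seg$cells))
  for (i in seq_len(nrow(seg$cells))) {
    d <- sqrt((sc$truth$cells$x_um / cfg$pixel_size - seg$cells$x_px[i])^2 +
      (sc$truth$cells$y_um / cfg$pixel_size - seg$cells$y_px[i])^2)
    truth_dead[i] <- sc$truth$cells$dead[which.min(d)]
  }
  expect_equal(seg$cells$is_dead, truth_dead)
  expect_equal(sum(seg$cells$is_dead), round(0.25 * cfg$n_cells))
  # threshold sweep +/- 20% around the adaptive split leaves flags unchanged
  med <- seg$cells$interior_median
  th <- cytofreeze:::otsu_vector(med)
  for (fac in c(0.8, 1.2)) {
    expect_equal(med > th * fac, truth_dead)
  }
})

test_that("all-live scenes produce zero dead flags", {
  cfg <- small_scene_config(n_cells = 4L, dead_fraction = 0, seed = 19L)
  sc <- simulate_scene(cfg)
  pre <- prep_phloxine(sc)
  seg <- classify_dead(segment_cells(pre, cfg$pixel_size), pre, cfg$pixel_size)
  expect_true(all(!seg$cells$is_dead))
})

test_that("measure_cell recovers spherocylinder geometry within one pixel", {
  ps <- 0.1
  # rendered spherocylinder mask, axis-aligned
  h <- 160
  w <- 160
  mk_mask <- function(L, W, angle) {
    cx <- 8
    cy <- 8
    e <- cytofreeze:::cell_axis_endpoints(cx, cy, angle, L, W) / ps
    xs <- (col(matrix(0, h, w)) - 0.5)
    ys <- (row(matrix(0, h, w)) - 0.5)
    matrix(
      cytofreeze:::point_segment_dist(
        xs, ys, e["ax"], e["ay"], e["bx"], e["by"]
      ) <= W / 2 / ps,
      h, w
    )
  }
  m <- mk_mask(10, 4, 0)
  res <- measure_cell(m, ps)
  expect_equal(unname(res["length_um"]), 10, tolerance = 0.1 / 10)
  expect_equal(unname(res["width_um"]), 4, tolerance = 0.1 / 4)
  # rotation invariance within one pixel
  res37 <- measure_cell(mk_mask(10, 4, 37 * pi / 180), ps)
  expect_lt(abs(res37[["length_um"]] - res[["length_um"]]), 0.1)
  expect_lt(abs(res37[["width_um"]] - res[["width_um"]]), 0.1)
  # perfect disc: length = width = diameter
  disc <- mk_mask(5, 5, 0)
  resd <- measure_cell(disc, ps)
  expect_equal(unname(resd["length_um"]), 5, tolerance = 0.12 / 5)
  expect_equal(unname(resd["width_um"]), 5, tolerance = 0.12 / 5)
  # tiny masks error
  expect_error(measure_cell(matrix(c(TRUE, rep(FALSE, 24)), 5, 5), ps))
})
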