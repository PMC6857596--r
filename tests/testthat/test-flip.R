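# FLIP curve extraction, bleach correction, normalisation, aggregation.

test_that("region means are exact on constructed stacks", {
  arr <- array(7, dim = c(32, 32, 1, 3))
  st <- timelapse_stack(arr, pixel_size = 0.1, frame_interval = 1)
  reg <- list(x_um = 1.6, y_um = 1.6, side_um = 0.6)
  reg2 <- list(x_um = 2.4, y_um = 1.0, side_um = 0.6)
  rm_ <- extract_region_means(st, reg, reg2)
  expect_true(all(rm_$bleach == 7))
  expect_true(all(rm_$reference == 7))
  # region of known rendered content
  arr2 <- arr
  arr2[10:12, 10:12, 1, 2] <- 21
  st2 <- timelapse_stack(arr2, 0.1, 1)
  regk <- list(x_um = 1.05, y_um = 1.05, side_um = 0.3)
  rmk <- extract_region_means(st2, regk, reg2)
  expect_equal(rmk$bleach[2], mean(arr2[10:12, 10:12, 1, 2]))
  # errors: region outside image / empty region
  expect_error(extract_region_means(st, list(x_um = 5, y_um = 1, side_um = 1), reg2))
})

test_that("bleach correction and normalisation behave as constructed", {
  # control constant, raw constant -> flat at 1
  c1 <- correct_and_normalize(rep(5, 10), rep(3, 10), prebleach_index = 3)
  expect_true(all(c1$normalised == 1))
  expect_equal(c1$normalised[3], 1)
  # raw halves while control constant -> final 0.5
  raw <- c(rep(4, 3), seq(4, 2, length.out = 7))
  c2 <- correct_and_normalize(raw, rep(3, 10), prebleach_index = 3)
  expect_equal(tail(c2$normalised, 1), 0.5)
  # pure acquisition bleaching cancels: both decay x0.8
  decay <- 0.8^(0:9)
  c3 <- correct_and_normalize(5 * decay, 3 * decay, prebleach_index = 1)
  expect_equal(c3$normalised, rep(1, 10), tolerance = 1e-12)
  # normalisation invariant to global intensity scaling
  c4 <- correct_and_normalize(50 * decay, 3 * decay, prebleach_index = 1)
  expect_equal(c4$normalised, c3$normalised, tolerance = 1e-12)
  # errors
  expect_error(correct_and_normalize(raw, rep(0, 10), prebleach_index = 3))
  expect_error(correct_and_normalize(raw, rep(3, 10), prebleach_index = 11))
})

test_that("exponential-fit correction recovers a pure acquisition decay", {
  times <- 0:19
  raw <- 10 * exp(-0.03 * times)
  cv <- correct_and_normalize(raw,
    prebleach_index = 10, times = times,
    method = "expfit"
  )
  expect_equal(cv$normalised, rep(1, 20), tolerance = 1e-9)
})

test_that("aggregation reports pointwise means with analytic CI width", {
  mk <- function(vals) {
    data.frame(t_s = seq_along(vals) - 1, normalised = vals)
  }
  agg <- aggregate_flip(list(mk(rep(0.4, 5)), mk(rep(0.6, 5))))
  expect_true(all(agg$summary$mean == 0.5))
  # identical curves: zero-width CI
  agg2 <- aggregate_flip(list(mk(rep(0.7, 5)), mk(rep(0.7, 5))))
  expect_true(all(agg2$summary$ci_hi - agg2$summary$ci_lo == 0))
  # i.i.d. noise: CI half-width ~ 1.96 sigma / sqrt(n)
  set.seed(20)
  sigma <- 0.1
  n <- 200
  curves <- lapply(seq_len(n), function(i) mk(rnorm(30, 1, sigma)))
  agg3 <- aggregate_flip(curves)
  hw <- (agg3$summary$ci_hi - agg3$summary$ci_lo) / 2
  expect_equal(mean(hw), 1.96 * sigma / sqrt(n), tolerance = 0.1)
  expect_error(aggregate_flip(list()))
  expect_error(aggregate_flip(list(mk(rep(1, 3)), mk(rep(1, 4)))))
})

test_that("simulated FLIP scenes show the mobile/immobile contrast", {
  cfg <- small_flip_config(seed = 31L)
  fs <- simulate_flip_stack(cfg, diffusion_coeff = 2)
  curve <- run_flip_analysis(
    fs$stack, fs$bleach_region, fs$reference_region,
    fs$prebleach_index,
    control_region = fs$control_region
  )
  expect_identical(curve$normalised[fs$prebleach_index], 1)
  expect_lt(tail(curve$normalised, 1), 0.2)
  # depletion is monotone after smoothing over two bleach periods
  post <- curve$normalised[curve$frame > fs$prebleach_index]
  cyc <- rep(seq_len(ceiling(length(post) / 10)), each = 10)[seq_along(post)]
  cm <- tapply(post, cyc, mean)
  expect_true(all(diff(cm) < 0.02))
  # immobile pool: reference stays within noise of 1
  cfgi <- small_flip_config(mobile_fraction = 0, seed = 33L)
  fsi <- simulate_flip_stack(cfgi, diffusion_coeff = 2)
  ci <- run_flip_analysis(
    fsi$stack, fsi$bleach_region, fsi$reference_region,
    fsi$prebleach_index,
    control_region = fsi$control_region
  )
  expect_true(all(abs(ci$normalised - 1) < 0.15))
})

test_that("bleach pulses only remove emitters inside the bleach region", {
  # efficiency 0: nothing removed, reference constant up to noise
  cfg0 <- small_flip_config(
    bleach_efficiency = 0, duration = 30,
    n_emitters = 2000L, seed = 41L
  )
  fs0 <- simulate_flip_stack(cfg0, diffusion_coeff = 2)
  expect_true(all(fs0$truth$alive == cfg0$n_emitters * 2))
  # immobile pool, disjoint regions: reference truth never decreases
  cfgi <- small_flip_config(
    mobile_fraction = 0, duration = 30,
    n_emitters = 2000L, seed = 43L
  )
  fsi <- simulate_flip_stack(cfgi, diffusion_coeff = 2)
  expect_true(all(diff(fsi$truth$reference_count) == 0))
})
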