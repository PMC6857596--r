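#' Spherocylinder volume
#'
#' Volume of a rod-shaped cell modelled as a cylinder plus a ball (the two
#' hemispherical cell ends): `V = pi (W/2)^2 (L - W) + (4/3) pi (W/2)^3`,
#' with `L` the total length and `W` the width (= cap diameter), both in
#' micrometres. Vectorised.
#'
#' @param L Cell length, um (`L >= W`).
#' @param W Cell width, um (positive).
#' @return Volume in um^3.
#' @export
spherocylinder_volume <- function(L, W) {
  if (any(W <= 0) || any(L <= 0)) stop("non-positive inputs")
  if (any(L < W)) stop("L < W")
  pi * (W / 2)^2 * (L - W) + (4 / 3) * pi * (W / 2)^3
}

#' Gaussian error propagation for the spherocylinder volume
#'
#' `dV^2 = (dV/dL)^2 dL^2 + (dV/dW)^2 dW^2` with the partial derivatives of
#' the cylinder-plus-ball volume evaluated at `(L, W)`:
#' `dV/dL = pi W^2 / 4` and `dV/dW = pi W (2L - W) / 4`.
#'
#' @param L,W Mean length and width, um.
#' @param dL2,dW2 Variances of the means, um^2 (non-negative).
#' @return Volume variance, um^6.
#' @export
volume_variance <- function(L, W, dL2, dW2) {
  if (any(dL2 < 0) || any(dW2 < 0)) stop("variances must be >= 0")
  if (any(W <= 0) || any(L < W)) stop("invalid geometry")
  dVdL <- pi * W^2 / 4
  dVdW <- pi * W * (2 * L - W) / 4
  dVdL^2 * dL2 + dVdW^2 * dW2
}

#' Bootstrap mean and variance of the mean
#'
#' Resamples `samples` with replacement `B` times at the original size and
#' returns the mean and variance across the `B` resample means.
#' Deterministic for a fixed seed.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param B Number of bootstrap resamples (default 999).
#' @param seed Integer seed.
#' @return List `mean`, `var`, `boot_means` (length `B`).
#' @export
bootstrap_mean <- function(samples, B = 999L, seed = 1L) {
  n <- length(samples)
  if (n == 0) stop("empty sample")
  if (n < 2) stop("need >= 2 samples")
  set.seed(seed)
  bm <- vapply(
    seq_len(B),
    function(b) mean(samples[sample.int(n, n, replace = TRUE)]),
    numeric(1)
  )
  list(mean = mean(bm), var = var(bm), boot_means = bm)
}

# Bootstrap of a pooled mean over independent experiments: each experiment
# is resampled independently, the per-experiment means are averaged, and the
# B pooled means summarised.
bootstrap_experiment_means <- function(values, experiment_id, B = 999L,
                                       seed = 1L) {
  sp <- split(values, experiment_id)
  set.seed(seed)
  bm <- vapply(seq_len(B), function(b) {
    mean(vapply(sp, function(v) {
      mean(v[sample.int(length(v), length(v), replace = TRUE)])
    }, numeric(1)))
  }, numeric(1))
  list(mean = mean(bm), var = var(bm), boot_means = bm)
}

#' Per-condition morphometry summary with bootstrap variances
#'
#' For each condition: every experiment's length and width samples are
#' bootstrap-resampled independently (`B` resamples), the per-experiment
#' means pooled into `B` bootstrapped means, and the mean and variance of
#' those pooled means reported (`Lbar, dL2, Wbar, dW2`). The mean cell
#' volume `V` is computed from `(Lbar, Wbar)` with
#' [spherocylinder_volume()] and its variance `dV2` by Gaussian error
#' propagation ([volume_variance()]).
#'
#' @param table Data frame `condition, experiment_id, length_um, width_um`.
#' @param B Bootstrap resamples per experiment.
#' @param seed Integer seed.
#' @return Data frame, one row per condition: `condition, n_cells,
#'   n_experiments, L, dL2, W, dW2, V, dV2`.
#' @export
morphometry_summary <- function(table, B = 999L, seed = 1L) {
  stopifnot(all(c("condition", "experiment_id", "length_um", "width_um")
  %in% names(table)))
  conds <- unique(table$condition)
  rows <- lapply(seq_along(conds), function(ci) {
    sub <- table[table$condition == conds[ci], ]
    bl <- bootstrap_experiment_means(
      sub$length_um, sub$experiment_id, B,
      seed = derive_seed(seed, 2L * ci)
    )
    bw <- bootstrap_experiment_means(
      sub$width_um, sub$experiment_id, B,
      seed = derive_seed(seed, 2L * ci + 1L)
    )
    data.frame(
      condition = conds[ci],
      n_cells = nrow(sub),
      n_experiments = length(unique(sub$experiment_id)),
      L = bl$mean, dL2 = bl$var,
      W = bw$mean, dW2 = bw$var,
      V = spherocylinder_volume(bl$mean, bw$mean),
      dV2 = volume_variance(bl$mean, bw$mean, bl$var, bw$var)
    )
  })
  do.call(rbind, rows)
}

#' Shrinkage ratio with Gaussian error propagation
#'
#' Ratio of a treated-condition mean to a control mean, `R = S / E`, with
#' variance `dR^2 = dS^2 / E^2 + (S^2 / E^4) dE^2` and a 95% confidence
#' interval `R +/- 1.96 sqrt(dR^2)` (normal approximation on the
#' bootstrapped means).
#'
#' @param S,E Condition means (treated, control); `E > 0`, `S > 0`.
#' @param dS2,dE2 Variances of the means.
#' @return List `R, dR2, ci95` (length-2 vector).
#' @export
shrinkage_ratio <- function(S, E, dS2 = 0, dE2 = 0) {
  if (E == 0) stop("E = 0")
  stopifnot(E > 0, S > 0, dS2 >= 0, dE2 >= 0)
  R <- S / E
  dR2 <- dS2 / E^2 + (S^2 / E^4) * dE2
  ci <- R + c(-1.96, 1.96) * sqrt(dR2)
  list(R = R, dR2 = dR2, ci95 = ci)
}

#' Length, width and volume shrinkage ratios between two conditions
#'
#' Computes `R = S/E` with propagated variance and 95% CI for cell length,
#' width and spherocylinder volume, from a [morphometry_summary()] table.
#'
#' @param summary Output of [morphometry_summary()].
#' @param cond_s Treated (e.g. hypertonic) condition name.
#' @param cond_e Control condition name.
#' @return Data frame `quantity, S, E, R, dR2, ci_lo, ci_hi`.
#' @export
shrinkage_analysis <- function(summary, cond_s, cond_e) {
  rs <- summary[summary$condition == cond_s, ]
  re <- summary[summary$condition == cond_e, ]
  stopifnot(nrow(rs) == 1, nrow(re) == 1)
  quantities <- list(
    length = c("L", "dL2"),
    width = c("W", "dW2"),
    volume = c("V", "dV2")
  )
  rows <- lapply(names(quantities), function(q) {
    cols <- quantities[[q]]
    sr <- shrinkage_ratio(
      rs[[cols[1]]], re[[cols[1]]],
      rs[[cols[2]]], re[[cols[2]]]
    )
    data.frame(
      quantity = q, S = rs[[cols[1]]], E = re[[cols[1]]],
      R = sr$R, dR2 = sr$dR2, ci_lo = sr$ci95[1], ci_hi = sr$ci95[2]
    )
  })
  do.call(rbind, rows)
}

#' Simulate per-cell morphometry measurement tables for two conditions
#'
#' Generates the measurement table a shrinkage experiment produces: for each
#' of `n_experiments` independent experiments, `n_cells` cells are drawn
#' with normally distributed lengths and widths (width truncated below the
#' length); the treated condition applies multiplicative shrink factors to
#' both dimensions. A small between-experiment offset models day-to-day
#' variability. Default shrink factors reproduce the magnitude of
#' hypertonic shrinkage of exponentially growing fission yeast (roughly 45%
#' volume loss).
#'
#' @param n_experiments,n_cells Experiments per condition, cells each.
#' @param L_mean,L_sd,W_mean,W_sd Length/width population parameters, um.
#' @param shrink_length,shrink_width Multiplicative factors applied to the
#'   treated condition.
#' @param between_exp_sd Standard deviation of the per-experiment mean
#'   offset, um.
#' @param conditions Names of (control, treated) conditions.
#' @param seed Integer seed.
#' @return List: `table` (data frame `condition, experiment_id, cell_id,
#'   length_um, width_um`), `true_ratio` (data frame with the population
#'   length/width/volume ratios implied by the shrink factors).
#' @export
simulate_morphometry_tables <- function(n_experiments = 3L, n_cells = 150L,
                                        L_mean = 10, L_sd = 1,
                                        W_mean = 4, W_sd = 0.3,
                                        shrink_length = 0.87,
                                        shrink_width = 0.79,
                                        between_exp_sd = 0.05,
                                        conditions = c("control", "sorbitol"),
                                        seed = 1L) {
  stopifnot(shrink_length > 0, shrink_width > 0, n_cells >= 2)
  set.seed(seed)
  rows <- list()
  for (cond_i in 1:2) {
    sl <- if (cond_i == 1) 1 else shrink_length
    sw <- if (cond_i == 1) 1 else shrink_width
    for (e in seq_len(n_experiments)) {
      off_l <- rnorm(1, 0, between_exp_sd)
      off_w <- rnorm(1, 0, between_exp_sd / 2)
      L <- rnorm(n_cells, L_mean * sl + off_l, L_sd * sl)
      W <- rnorm(n_cells, W_mean * sw + off_w, W_sd * sw)
      bad <- which(W >= L | W <= 0 | L <= 0)
      while (length(bad)) {
        L[bad] <- rnorm(length(bad), L_mean * sl + off_l, L_sd * sl)
        W[bad] <- rnorm(length(bad), W_mean * sw + off_w, W_sd * sw)
        bad <- bad[W[bad] >= L[bad] | W[bad] <= 0 | L[bad] <= 0]
      }
      rows[[length(rows) + 1]] <- data.frame(
        condition = conditions[cond_i],
        experiment_id = paste0("exp", e),
        cell_id = seq_len(n_cells),
        length_um = L, width_um = W
      )
    }
  }
  true_ratio <- data.frame(
    quantity = c("length", "width", "volume"),
    R = c(
      shrink_length, shrink_width,
      spherocylinder_volume(L_mean * shrink_length, W_mean * shrink_width) /
        spherocylinder_volume(L_mean, W_mean)
    )
  )
  list(table = do.call(rbind, rows), true_ratio = true_ratio)
}
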