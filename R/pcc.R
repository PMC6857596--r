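#' Droplet probability map
#'
#' Converts a registered, log-transformed and background-subtracted frame
#' into a per-pixel droplet probability in `[0, 1]`: a band-pass spot
#' response (difference of Gaussians at `spot_sigma` and `2 * spot_sigma`)
#' is normalised by a high quantile of its positive values and squashed
#' through a logistic. The normalisation makes the map insensitive to global
#' intensity scaling — the property the equalisation chain exists for — and
#' the output is monotone in the spot response and fully deterministic.
#'
#' @param frame_pre Preprocessed frame (see [log_background_subtract()]).
#' @param spot_sigma Spot scale, px (positive).
#' @param gain,offset Logistic parameters: `p = plogis(gain * (r - offset))`
#'   with `r` the normalised response. Calibrated once on synthetic
#'   fixtures; a blank frame maps to `plogis(-gain * offset) <= 0.5`.
#' @param norm_quantile Quantile of the positive responses used as the
#'   normalisation scale.
#' @return Numeric matrix in `[0, 1]` with attribute `params`.
#' @export
droplet_probability_map <- function(frame_pre, spot_sigma = 1.2,
                                    gain = 8, offset = 0.35,
                                    norm_quantile = 0.999) {
  stopifnot(spot_sigma > 0)
  resp <- gauss_blur(frame_pre, spot_sigma) -
    gauss_blur(frame_pre, 2 * spot_sigma)
  pos <- resp[resp > 0]
  scale <- if (length(pos)) quantile(pos, norm_quantile, names = FALSE) else 0
  scale <- max(scale, 1e-8)
  p <- plogis(gain * (resp / scale - offset))
  attr(p, "params") <- list(
    spot_sigma = spot_sigma, gain = gain, offset = offset,
    norm_quantile = norm_quantile, scale = scale
  )
  p
}

#' Per-cell temporal Pearson correlation (PCC)
#'
#' The core mobility statistic: the Pearson correlation coefficient
#' `r = sum((a - mean(a)) (b - mean(b))) / sqrt(sum((a - mean(a))^2) *
#' sum((b - mean(b))^2))` computed over exactly the pixels of one cell mask
#' between two probability maps separated in time (frames 2 and 3 of a
#' triplet by default — frame 1 is skipped because of the early intensity
#' drift). `r = 1` means a completely static intensity distribution; more
#' particle displacement lowers it. A cell with zero variance in either map
#' is dropped with a logged reason rather than returning an undefined value.
#'
#' @param map_a,map_b Probability maps on a common registered grid.
#' @param cell_mask Logical matrix selecting the cell's pixels.
#' @param min_pixels Minimum pixel count for a valid PCC.
#' @param label Optional cell label carried through.
#' @return One-row data frame `label, r, n_pixels, reason` (`reason` is `NA`
#'   for a valid value, otherwise `"zero_variance"` or `"too_few_pixels"`
#'   with `r = NA`).
#' @export
cell_pcc <- function(map_a, map_b, cell_mask, min_pixels = 20L, label = NA) {
  stopifnot(all(dim(map_a) == dim(map_b)), all(dim(map_a) == dim(cell_mask)))
  a <- as.numeric(map_a[cell_mask])
  b <- as.numeric(map_b[cell_mask])
  n <- length(a)
  if (n < min_pixels) {
    return(data.frame(
      label = label, r = NA_real_, n_pixels = n,
      reason = "too_few_pixels"
    ))
  }
  ac <- a - mean(a)
  bc <- b - mean(b)
  sa <- sum(ac * ac)
  sb <- sum(bc * bc)
  if (sa == 0 || sb == 0) {
    return(data.frame(
      label = label, r = NA_real_, n_pixels = n,
      reason = "zero_variance"
    ))
  }
  r <- sum(ac * bc) / sqrt(sa * sb)
  r <- min(1, max(-1, r))
  data.frame(label = label, r = r, n_pixels = n, reason = NA_character_)
}

#' Population statistics of per-cell PCC values
#'
#' Summarises per-cell PCC values grouped by independent experiment: the
#' median of each experiment, the mean of those medians, and — when at least
#' three experiments are present — a normal-approximation 95% confidence
#' interval of the medians (`mean +/- 1.96 * SE`). With fewer than three
#' experiments the interval is reported as unavailable. The normal
#' approximation matches the convention of plotting the mean of per-culture
#' medians with its CI; it can underestimate the true variance of a median.
#'
#' @param pcc_results Data frame with columns `experiment_id` and `r`
#'   (rows with `NA` are dropped).
#' @param value Name of the value column.
#' @return List of class `pcc_population_summary`: `medians` (named),
#'   `mean_of_medians`, `ci95` (length-2 or `NA`), `n_cells` per experiment.
#' @export
population_pcc_stats <- function(pcc_results, value = "r") {
  stopifnot("experiment_id" %in% names(pcc_results))
  df <- pcc_results[!is.na(pcc_results[[value]]), ]
  if (nrow(df) == 0) stop("empty group: no valid values")
  sp <- split(df[[value]], df$experiment_id)
  medians <- vapply(sp, median, numeric(1))
  n_cells <- vapply(sp, length, integer(1))
  m <- mean(medians)
  k <- length(medians)
  ci <- if (k >= 3) {
    se <- sd(medians) / sqrt(k)
    c(m - 1.96 * se, m + 1.96 * se)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(
      medians = medians, mean_of_medians = m, ci95 = ci,
      n_cells = n_cells, n_experiments = k
    ),
    class = "pcc_population_summary"
  )
}

#' @export
print.pcc_population_summary <- function(x, ...) {
  cat(sprintf(
    "PCC population summary: %d experiment(s), %d cells\n",
    x$n_experiments, sum(x$n_cells)
  ))
  cat(sprintf("  mean of medians: %.4f\n", x$mean_of_medians))
  if (!is.na(x$ci95[1])) {
    cat(sprintf("  95%% CI of medians: [%.4f, %.4f]\n", x$ci95[1], x$ci95[2]))
  } else {
    cat("  95% CI of medians: unavailable (<3 experiments)\n")
  }
  invisible(x)
}
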