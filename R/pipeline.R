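#' Per-cell PCC mobility quantification of a two-channel triplet
#'
#' The full mobility pipeline for one acquisition: segment cells from the
#' phloxine channel (preprocessed with [log_background_subtract()]), flag
#' dead cells, register the droplet-channel frames to frame 1, preprocess
#' and convert the two analysis frames (by default frames 2 and 3 — frame 1
#' carries the early intensity drift) into droplet probability maps, and
#' compute the per-cell PCC over every live cell's pixels. Dead cells are
#' never assigned a PCC.
#'
#' @param stack A two-channel `timelapse_stack` with >= 3 droplet frames
#'   (channels `droplet`, `phloxine`).
#' @param experiment_id Identifier attached to every cell row.
#' @param frames_used Length-2 frame pair for the correlation (default
#'   `c(2, 3)`; `c(1, 2)` available for sensitivity analysis).
#' @param background_scale Background sigma for preprocessing, px.
#' @param spot_sigma Probability-map spot scale, px.
#' @param min_pixels Minimum cell pixels for a valid PCC.
#' @param ... Further arguments to [droplet_probability_map()].
#' @return List of class `pcc_scene_result`: `cells` (segmentation table
#'   with `r`, `n_pixels`, `reason`, `experiment_id`; dead cells keep
#'   `r = NA` and reason `"dead_cell"`), `labels`, `shifts`, `maps` (the two
#'   probability maps).
#' @export
run_pcc_scene <- function(stack, experiment_id = "exp1",
                          frames_used = c(2L, 3L),
                          background_scale = 20, spot_sigma = 1.2,
                          min_pixels = 20L, ...) {
  stopifnot(inherits(stack, "timelapse_stack"), n_channels(stack) >= 2)
  stopifnot(length(frames_used) == 2, max(frames_used) <= n_frames(stack))
  phlox <- get_frame(stack, 1L, "phloxine")
  phlox_pre <- log_background_subtract(phlox, background_scale)
  seg <- segment_cells(phlox_pre, stack$pixel_size)
  seg <- classify_dead(seg, phlox_pre, stack$pixel_size)
  reg <- register_translation(stack, channel = which(
    stack$channel_names == "droplet"
  ))
  maps <- lapply(frames_used, function(f) {
    droplet_probability_map(
      log_background_subtract(reg$frames[, , f], background_scale),
      spot_sigma = spot_sigma, ...
    )
  })
  cells <- seg$cells
  cells$experiment_id <- experiment_id
  cells$r <- NA_real_
  cells$n_pixels <- NA_integer_
  cells$reason <- NA_character_
  for (i in seq_len(nrow(cells))) {
    if (isTRUE(cells$is_dead[i])) {
      cells$reason[i] <- "dead_cell"
      next
    }
    mask <- seg$labels == cells$label[i]
    res <- cell_pcc(maps[[1]], maps[[2]], mask,
      min_pixels = min_pixels, label = cells$label[i]
    )
    cells$r[i] <- res$r
    cells$n_pixels[i] <- res$n_pixels
    cells$reason[i] <- res$reason
  }
  structure(
    list(
      cells = cells, labels = seg$labels, shifts = reg$shifts,
      maps = maps, frames_used = frames_used
    ),
    class = "pcc_scene_result"
  )
}

#' Track particles through a droplet-channel movie
#'
#' Registers the movie, detects particles in every frame
#' ([detect_particles()]) and links them into trajectories
#' ([link_tracks()]). Optionally restricts trajectories to live cells when a
#' label matrix and cell table are supplied (trajectories starting in a
#' dead cell or background are dropped).
#'
#' @param stack A `timelapse_stack`; `channel` selects the movie channel.
#' @param channel Channel index or name.
#' @param radius_px,quality_cutoff Detection parameters.
#' @param max_displacement_px,gap_max Linking parameters.
#' @param register Register frames to frame 1 first.
#' @param labels Optional label matrix from [segment_cells()].
#' @param cells Optional cell table with `label` and `is_dead`.
#' @return Trajectories data frame as from [link_tracks()].
#' @export
track_movie <- function(stack, channel = 1L, radius_px = 4,
                        quality_cutoff = NULL,
                        max_displacement_px = 4, gap_max = 3,
                        register = FALSE, labels = NULL, cells = NULL) {
  frames <- stack$data[, , if (is.character(channel)) {
    match(channel, stack$channel_names)
  } else {
    channel
  }, , drop = TRUE]
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (register) {
    frames <- register_translation(frames)$frames
  }
  det <- lapply(seq_len(dim(frames)[3]), function(f) {
    detect_particles(frames[, , f], radius_px, quality_cutoff)
  })
  tr <- link_tracks(det,
    max_displacement_px = max_displacement_px, gap_max = gap_max,
    pixel_size = stack$pixel_size, frame_interval = stack$frame_interval,
    labels = labels
  )
  if (!is.null(labels) && !is.null(cells) && nrow(tr) > 0) {
    dead_labels <- cells$label[isTRUE_vec(cells$is_dead)]
    drop <- is.na(tr$cell_label) | tr$cell_label == 0 |
      tr$cell_label %in% dead_labels
    tr <- tr[!drop, , drop = FALSE]
    attr(tr, "pixel_size") <- stack$pixel_size
    attr(tr, "frame_interval") <- stack$frame_interval
  }
  tr
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Analyse a FLIP scene end to end
#'
#' Extracts the reference- and bleach-region curves from a FLIP stack,
#' bleach-corrects and normalises the reference curve, and returns the
#' curve together with the regions used.
#'
#' @param stack A `timelapse_stack` (FLIP series).
#' @param bleach_region,reference_region Square regions (`x_um, y_um,
#'   side_um`).
#' @param prebleach_index Index of the last pre-bleach frame.
#' @param control Optional control-cell curve (numeric, same grid).
#' @param control_region Optional region of an unbleached control cell; its
#'   mean curve is extracted from the stack and used as `control`. Without
#'   either, the mono-exponential acquisition-bleach fit is used.
#' @param z_mode Plane handling, see [extract_region_means()].
#' @param cell_id Identifier carried through.
#' @return A `flip_curve` data frame (reference region), with the raw
#'   region means attached as attribute `region_means`.
#' @export
run_flip_analysis <- function(stack, bleach_region, reference_region,
                              prebleach_index, control = NULL,
                              control_region = NULL,
                              z_mode = "single", cell_id = NA) {
  rm_ <- extract_region_means(stack, bleach_region, reference_region,
    z_mode = z_mode
  )
  if (is.null(control) && !is.null(control_region)) {
    cm <- extract_region_means(stack, control_region, control_region,
      z_mode = z_mode
    )
    control <- cm$reference
  }
  method <- if (is.null(control)) "expfit" else "control"
  curve <- correct_and_normalize(rm_$reference,
    control = control,
    prebleach_index = prebleach_index,
    times = rm_$t_s, method = method, cell_id = cell_id
  )
  attr(curve, "region_means") <- rm_
  curve
}
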