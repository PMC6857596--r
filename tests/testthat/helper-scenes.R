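# Shared fixture builders: small scenes kept fast enough for routine runs.

small_scene_config <- function(...) {
  args <- list(
    image_shape = c(192L, 192L), n_cells = 4L,
    cell_length_range = c(7, 9), cell_width_range = c(3, 4),
    seed = 42L
  )
  args[names(list(...))] <- list(...)
  do.call(scene_config, args)
}

# One large "arena" cell so that free diffusion is effectively unbounded
# over short runs (used for analytic MSD oracles).
arena_cell <- function(size_um = 60) {
  data.frame(
    cell = 1L, x_um = size_um, y_um = size_um, angle = 0,
    length_um = 1.5 * size_um, width_um = size_um
  )
}

# Hand-built trajectory data frame.
make_traj <- function(id, frames, x, y) {
  data.frame(particle_id = id, frame = frames, x_um = x, y_um = y)
}

small_flip_config <- function(...) {
  args <- list(n_emitters = 3000L, seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(flip_scene_config, args)
}
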