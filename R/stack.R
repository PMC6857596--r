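#' Time-lapse image stack container
#'
#' A light container for a multi-frame, one- or multi-channel grayscale image
#' sequence with the acquisition metadata downstream analyses need (pixel
#' size in micrometres per pixel, frame interval in seconds). Pixel data are
#' stored as a 4-D numeric array `[row, col, channel, frame]` in arbitrary
#' count units.
#'
#' @param data Numeric 4-D array `[H, W, C, T]` (a matrix or 3-D array is
#'   promoted, assuming one channel and/or one frame).
#' @param pixel_size Pixel size in um/px (positive scalar).
#' @param frame_interval Frame interval in seconds (positive scalar).
#' @param channel_names Optional character vector of length C.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(data, pixel_size, frame_interval,
                            channel_names = NULL) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  stopifnot(
    length(dim(data)) == 4L, is.numeric(data),
    is.numeric(pixel_size), pixel_size > 0,
    is.numeric(frame_interval), frame_interval > 0
  )
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(dim(data)[3]))
  }
  stopifnot(length(channel_names) == dim(data)[3])
  structure(
    list(
      data = data,
      pixel_size = pixel_size,
      frame_interval = frame_interval,
      channel_names = channel_names
    ),
    class = "timelapse_stack"
  )
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "timelapse_stack: %d x %d px, %d channel(s) [%s], %d frame(s)\n",
    d[1], d[2], d[3], paste(x$channel_names, collapse = ", "), d[4]
  ))
  cat(sprintf(
    "  pixel size %g um/px, frame interval %g s\n",
    x$pixel_size, x$frame_interval
  ))
  invisible(x)
}

#' Number of frames / channels of a stack
#' @param stack A `timelapse_stack`.
#' @return Integer count.
#' @export
n_frames <- function(stack) dim(stack$data)[4]

#' @rdname n_frames
#' @export
n_channels <- function(stack) dim(stack$data)[3]

#' Extract one frame of one channel as a matrix
#'
#' @param stack A `timelapse_stack`.
#' @param frame Frame index (1-based).
#' @param channel Channel index or name.
#' @return Numeric matrix `[H, W]`.
#' @export
get_frame <- function(stack, frame, channel = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
  }
  stopifnot(
    frame >= 1, frame <= n_frames(stack),
    !is.na(channel), channel >= 1, channel <= n_channels(stack)
  )
  stack$data[, , channel, frame]
}

# Fixed full-scale used when serialising count-valued images to TIFF, which
# stores values in [0, 1].
.tiff_full_scale <- 4096

#' Write / read a time-lapse stack as multi-page TIFF plus JSON metadata
#'
#' Pages are interleaved frame-major (`t1c1, t1c2, t2c1, ...`). Values are
#' scaled by a fixed full-scale into `[0, 1]` and written as 32-bit float; a
#' JSON sidecar (`<path>.json`) carries pixel size, frame interval, channel
#' names and the scale so that `read_stack_tiff()` restores the stack.
#'
#' @param stack A `timelapse_stack`.
#' @param path Output TIFF path.
#' @return `write_stack_tiff()` returns `path` invisibly; `read_stack_tiff()`
#'   returns a `timelapse_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$data)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (t in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      pages[[k]] <- pmin(pmax(stack$data[, , c, t] / .tiff_full_scale, 0), 1)
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(
    pixel_size = stack$pixel_size,
    frame_interval = stack$frame_interval,
    channel_names = as.list(stack$channel_names),
    n_channels = d[3],
    n_frames = d[4],
    full_scale = .tiff_full_scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  h <- nrow(pages[[1]])
  w <- ncol(pages[[1]])
  nc <- meta$n_channels
  nt <- meta$n_frames
  stopifnot(length(pages) == nc * nt)
  arr <- array(0, dim = c(h, w, nc, nt))
  k <- 1L
  for (t in seq_len(nt)) {
    for (c in seq_len(nc)) {
      arr[, , c, t] <- pages[[k]] * meta$full_scale
      k <- k + 1L
    }
  }
  timelapse_stack(arr, meta$pixel_size, meta$frame_interval,
    channel_names = meta$channel_names
  )
}
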