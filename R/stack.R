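#' Calibrated timelapse image stack
#'
#' Container for a T x Z x C x Y x X intensity array with spatial and
#' temporal calibration and channel roles. Intensities must be finite and
#' non-negative.
#'
#' @param voxels 5-dimensional numeric array, dimensions ordered
#'   `(T, Z, C, Y, X)`.
#' @param pixel_size_um pixel size (um).
#' @param frame_interval_min time between frames (min).
#' @param channel_roles named integer vector mapping channel roles (e.g.
#'   `tag`, `chromatin`) to channel indices.
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(voxels, pixel_size_um, frame_interval_min,
                            channel_roles = c(tag = 1L)) {
  if (!is.array(voxels) || length(dim(voxels)) != 5)
    stop_param("'voxels' must be a 5-D array (T, Z, C, Y, X)")
  if (any(dim(voxels) < 1)) stop_param("all stack dimensions must be >= 1")
  if (anyNA(voxels) || any(!is.finite(voxels)) || any(voxels < 0))
    stop_param("intensities must be finite and non-negative")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(frame_interval_min, "frame_interval_min")
  if (is.null(names(channel_roles)) ||
      any(channel_roles < 1 | channel_roles > dim(voxels)[3]))
    stop_param("'channel_roles' must name valid channel indices")
  structure(list(voxels = voxels,
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 channel_roles = channel_roles),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("timelapse_stack: %d frames x %d z x %d channels, %d x %d px\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel size %.3g um, frame interval %.3g min\n",
              x$pixel_size_um, x$frame_interval_min))
  cat("  channels:", paste(sprintf("%s=%d", names(x$channel_roles),
                                   x$channel_roles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.timelapse_stack <- function(x) dim(x$voxels)

# Fetch one 2-D frame (Y x X matrix) of a given channel/z.
stack_frame <- function(stack, frame, z, channel = "tag") {
  d <- dim(stack$voxels)
  ch <- if (is.character(channel)) stack$channel_roles[[channel]] else channel
  if (frame < 1 || frame > d[1]) stop_param("frame index out of range")
  if (z < 1 || z > d[2]) stop_param("z index out of range")
  if (is.null(ch) || ch < 1 || ch > d[3]) stop_param("unknown channel")
  matrix(stack$voxels[frame, z, ch, , ], d[4], d[5])
}

#' Write a timelapse stack as a multi-page TIFF plus JSON metadata
#'
#' Pages are ordered T-major, then Z, then C. Intensities are stored as
#' 32-bit floats scaled to `[0, 1]`; the scale and the calibration are
#' recorded in a JSON sidecar (`<path>.json`) so that
#' [read_stack_tiff()] restores the stack exactly.
#'
#' @param stack a [timelapse_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$voxels)
  mx <- max(stack$voxels, 1e-12)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    i <- i + 1
    pages[[i]] <- matrix(stack$voxels[t, z, ch, , ], d[4], d[5]) / mx
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(axes = "TZCYX", dim = as.integer(d), scale = mx,
               pixel_size_um = stack$pixel_size_um,
               frame_interval_min = stack$frame_interval_min,
               channel_roles = as.list(stack$channel_roles))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a timelapse stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (a `<path>.json` sidecar must exist).
#' @return A [timelapse_stack()].
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  vox <- array(0, dim = d)
  i <- 0
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    i <- i + 1
    vox[t, z, ch, , ] <- pages[[i]] * meta$scale
  }
  timelapse_stack(vox, meta$pixel_size_um, meta$frame_interval_min,
                  unlist(meta$channel_roles))
}
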