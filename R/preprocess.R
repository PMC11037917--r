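#' Subtract background from a frame
#'
#' Estimates the background level `b` as the mean over a background ROI when
#' one is supplied, or as a low percentile of the frame otherwise, and
#' returns `max(0, frame - b)`. The estimate is recorded in the
#' `"background"` attribute of the result for provenance.
#'
#' @param frame 2-D numeric matrix.
#' @param roi optional background ROI (see [roi_rect()]; logical masks and
#'   0-based coordinate matrices are also accepted).
#' @param percentile percentile used when no ROI is given (default 0.05).
#' @return The background-subtracted frame (negative values clamped to 0),
#'   with attribute `background`.
#' @export
subtract_background <- function(frame, roi = NULL, percentile = 0.05) {
  if (!is.matrix(frame)) stop_param("'frame' must be a matrix")
  b <- if (!is.null(roi)) mean(roi_values(frame, roi, "background roi"))
       else unname(stats::quantile(frame, percentile))
  if (b >= max(frame))
    warning("background estimate >= frame maximum; output is all zero")
  out <- pmax(frame - b, 0)
  attr(out, "background") <- b
  out
}

#' Ratio-based photobleaching correction
#'
#' Multiplies every frame `t` by `m1 / m_t`, where `m_t` is that frame's
#' mean intensity over a reference region, so that corrected region means
#' all equal the first frame's mean.
#'
#' @param stack a [timelapse_stack()].
#' @param region optional logical Y x X mask defining the reference region
#'   (default: the whole frame).
#' @param channel channel to correct (role name or index).
#' @return The corrected stack, with per-frame scale factors in the
#'   `"bleach_scale"` attribute.
#' @export
correct_bleach <- function(stack, region = NULL, channel = "tag") {
  d <- dim(stack$voxels)
  ch <- if (is.character(channel)) stack$channel_roles[[channel]] else channel
  if (is.null(ch)) stop_param("unknown channel")
  if (is.null(region)) region <- matrix(TRUE, d[4], d[5])
  if (!is.logical(region) || !all(dim(region) == d[4:5]))
    stop_param("'region' must be a logical Y x X mask")
  m <- numeric(d[1])
  for (t in seq_len(d[1])) {
    sl <- stack$voxels[t, , ch, , , drop = FALSE]
    sl <- array(sl, dim = c(d[2], d[4], d[5]))
    m[t] <- mean(apply(sl, 1, function(fr) mean(fr[region])))
  }
  if (any(m == 0))
    stop_param(sprintf("region mean is zero at frame %d", which(m == 0)[1]))
  scale <- m[1] / m
  out <- stack
  for (t in seq_len(d[1]))
    out$voxels[t, , ch, , ] <- stack$voxels[t, , ch, , ] * scale[t]
  attr(out, "bleach_scale") <- scale
  out
}

#' Average projection of two central z-slices
#'
#' @param stack a [timelapse_stack()].
#' @param frame timepoint index (1-based).
#' @param z_pair two z-slice indices to average.
#' @param channel channel role name or index.
#' @return A 2-D matrix: the pixel-wise mean of the two slices.
#' @export
project_central_z <- function(stack, frame, z_pair = NULL, channel = "tag") {
  d <- dim(stack$voxels)
  if (is.null(z_pair)) {
    zmid <- (d[2] + 1) / 2
    z_pair <- c(floor(zmid), ceiling(zmid))
    if (z_pair[1] == z_pair[2] && d[2] > 1) z_pair[2] <- z_pair[1] + 1
  }
  if (length(z_pair) != 2) stop_param("'z_pair' must contain two indices")
  (stack_frame(stack, frame, z_pair[1], channel) +
     stack_frame(stack, frame, z_pair[2], channel)) / 2
}

#' Segment the cell from a fluorescence frame
#'
#' Otsu threshold on the (optionally background-subtracted) frame, hole
#' filling, and selection of the largest connected component.
#'
#' @param frame 2-D numeric matrix.
#' @param subtract subtract the 5th-percentile background first.
#' @return Logical mask of the largest foreground component.
#' @export
segment_cell <- function(frame, subtract = TRUE) {
  img <- if (subtract) subtract_background(frame) else frame
  mx <- max(img)
  if (mx <= 0) stop_param("frame has no signal to segment")
  thr <- EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1)) * mx
  bin <- EBImage::fillHull(img > thr)
  lab <- EBImage::bwlabel(bin)
  if (max(lab) == 0) stop_param("no foreground component found")
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}
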