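# Cortical linescan quantification: a 5-pixel-wide line is traced along the
# cell cortex from pole to pole, intensities are sampled perpendicular to
# the path, positions are signed relative to the midplane, and the breadth
# of the equatorial peak is the extent of the contiguous above-half-maximum
# region converted to microns.

#' Construct a linescan profile
#'
#' @param position_um strictly increasing signed arc positions (um) relative
#'   to the midplane (position 0).
#' @param intensity non-negative intensities, same length.
#' @param spacing_um arc spacing between samples (um).
#' @param cortex_length_um total cortex path length (um).
#' @param normalized whether the profile has been peak-normalized.
#' @return An object of class `linescan_profile`.
#' @export
linescan_profile <- function(position_um, intensity, spacing_um,
                             cortex_length_um, normalized = FALSE) {
  if (length(position_um) != length(intensity))
    stop_param("position and intensity lengths differ")
  if (any(diff(position_um) <= 0))
    stop_param("'position_um' must be strictly increasing")
  if (any(intensity < 0)) stop_param("intensities must be non-negative")
  if (normalized && abs(max(intensity) - 1) > 1e-12)
    stop_param("normalized profile must have max intensity 1")
  structure(list(position_um = position_um, intensity = intensity,
                 spacing_um = spacing_um,
                 cortex_length_um = cortex_length_um,
                 normalized = normalized), class = "linescan_profile")
}

#' @export
print.linescan_profile <- function(x, ...) {
  cat(sprintf("linescan_profile: %d samples, %.3g um spacing, cortex %.3g um%s\n",
              length(x$intensity), x$spacing_um, x$cortex_length_um,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' @method plot linescan_profile
#' @export
plot.linescan_profile <- function(x, ...) {
  graphics::plot(x$position_um, x$intensity, type = "l",
                 xlab = "position from midplane (um)",
                 ylab = if (x$normalized) "normalized intensity" else "intensity",
                 ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

# Offset a closed polyline along its local normal; `delta > 0` moves
# outward (the pixel-centre contour of a rasterized mask sits half a pixel
# inside the true boundary).
offset_closed <- function(xy, delta) {
  if (delta == 0) return(xy)
  n <- nrow(xy)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  tx <- xy[nxt, 1] - xy[prv, 1]; ty <- xy[nxt, 2] - xy[prv, 2]
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  nx <- -ty / len; ny <- tx / len
  a <- xy + delta * cbind(nx, ny)
  b <- xy - delta * cbind(nx, ny)
  area <- function(p) abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]) / 2)
  if (area(a) >= area(b)) a else b
}

# Gaussian smoothing of a closed polyline's coordinates (used to undo the
# pixelation of a rasterized boundary before measuring arc lengths).
smooth_closed <- function(xy, sigma) {
  if (sigma <= 0) return(xy)
  n <- nrow(xy)
  half <- max(1, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- rbind(xy[(n - half + 1):n, , drop = FALSE], xy,
               xy[1:half, , drop = FALSE])
  out <- apply(pad, 2, function(v) stats::filter(v, k, sides = 2))
  out[(half + 1):(half + n), , drop = FALSE]
}

#' Trace the cortex path between two poles
#'
#' Extracts the ordered boundary of a single-component cell mask, smooths
#' away rasterization, and returns the boundary arc from `pole1` to `pole2`
#' on one designated side, resampled at a fixed arc step. A midplane line
#' (by default the perpendicular bisector of the pole-pole chord) defines
#' arc position zero; it must cross the path exactly once.
#'
#' @param cell_mask logical Y x X matrix with exactly one foreground
#'   component.
#' @param pole1,pole2 0-based `(x, y)` coordinates of the two poles; must lie
#'   within `snap_tol_px` of the (inset) boundary.
#' @param line_width_px width of the sampling line used later by
#'   [sample_linescan()] (default 5).
#' @param pixel_size_um pixel size (um).
#' @param sampling_step_px arc distance between path samples (pixels).
#' @param inset_px inward offset of the path from the mask boundary
#'   (pixels); use about half the cortex thickness so the sampling line is
#'   centred on the cortex shell.
#' @param side `"forward"` follows the boundary in contour orientation from
#'   `pole1` to `pole2`; `"backward"` takes the complementary arc.
#' @param midplane optional 2 x 2 matrix of two 0-based `(x, y)` points
#'   defining the midplane line.
#' @param smooth_sigma_px SD of the Gaussian smoothing applied to boundary
#'   coordinates (pixels).
#' @param snap_tol_px maximum allowed distance between a pole and the
#'   boundary.
#' @return An object of class `cortex_path`: resampled `vertices` (0-based
#'   x, y), signed `arc_pos_um`, `spacing_um`, `cortex_length_um`,
#'   `line_width_px`, the `midplane` used and `pixel_size_um`.
#' @export
extract_cortex_path <- function(cell_mask, pole1, pole2, line_width_px = 5,
                                pixel_size_um = 1, sampling_step_px = 1,
                                inset_px = 0, side = c("forward", "backward"),
                                midplane = NULL, smooth_sigma_px = 2,
                                snap_tol_px = 3) {
  side <- match.arg(side)
  if (!is.logical(cell_mask) || !is.matrix(cell_mask))
    stop_param("'cell_mask' must be a logical matrix")
  if (!any(cell_mask)) stop_param("empty cell mask")
  lab <- EBImage::bwlabel(cell_mask)
  if (max(lab) != 1) stop_param("cell mask must have exactly one component")
  m <- cell_mask
  if (inset_px > 0) {
    brush <- EBImage::makeBrush(2 * round(inset_px) + 1, shape = "disc")
    m <- EBImage::erode(cell_mask, brush) > 0
    if (!any(m)) stop_param("mask vanished under the requested inset")
  }
  oc <- EBImage::ocontour(m)[[1]]          # 0-based (dim1, dim2) = (y, x)
  contour <- cbind(x = oc[, 2], y = oc[, 1])
  contour <- smooth_closed(contour, smooth_sigma_px)
  contour <- offset_closed(contour, 0.5)
  n <- nrow(contour)

  snap <- function(pole, name) {
    d2 <- (contour[, 1] - pole[1])^2 + (contour[, 2] - pole[2])^2
    i <- which.min(d2)
    if (sqrt(d2[i]) > snap_tol_px + inset_px)
      stop_param(sprintf("'%s' is not on the mask boundary", name))
    i
  }
  i1 <- snap(pole1, "pole1"); i2 <- snap(pole2, "pole2")
  if (i1 == i2) stop_param("poles snap to the same boundary point")
  idx <- if (side == "forward") {
    if (i1 <= i2) i1:i2 else c(i1:n, 1:i2)
  } else {
    if (i1 >= i2) i1:i2 else c(i1:1, n:i2)
  }
  path <- contour[idx, , drop = FALSE]

  # resample at a constant arc step
  seg <- sqrt(rowSums(diff(path)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total <= 0) stop_param("degenerate path")
  s_out <- seq(0, total, by = sampling_step_px)
  vx <- stats::approx(arc, path[, 1], xout = s_out, rule = 2)$y
  vy <- stats::approx(arc, path[, 2], xout = s_out, rule = 2)$y
  vertices <- cbind(x = vx, y = vy)

  if (is.null(midplane)) {
    mid <- (pole1[1:2] + pole2[1:2]) / 2
    dir <- pole2[1:2] - pole1[1:2]
    nrm <- c(-dir[2], dir[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    L <- max(dim(cell_mask))
    midplane <- rbind(mid - L * nrm, mid + L * nrm)
  }
  # signed distance of each vertex from the midplane line
  a <- midplane[1, ]; b <- midplane[2, ]
  u <- b - a; u <- u / sqrt(sum(u^2))
  nvec <- c(-u[2], u[1])
  f <- (vertices[, 1] - a[1]) * nvec[1] + (vertices[, 2] - a[2]) * nvec[2]
  cross <- which(f[-length(f)] * f[-1] < 0 | f[-length(f)] == 0)
  cross <- cross[!(f[cross] == 0 & f[pmax(cross - 1, 1)] == 0)]
  if (length(cross) != 1)
    stop_param(sprintf("midplane crosses the path %d times (need exactly 1)",
                       length(cross)))
  i <- cross
  frac <- if (f[i] == 0) 0 else f[i] / (f[i] - f[i + 1])
  s0 <- s_out[i] + frac * (s_out[i + 1] - s_out[i])

  structure(list(vertices = vertices,
                 arc_pos_um = (s_out - s0) * pixel_size_um,
                 spacing_um = sampling_step_px * pixel_size_um,
                 cortex_length_um = total * pixel_size_um,
                 line_width_px = line_width_px,
                 sampling_step_px = sampling_step_px,
                 midplane = midplane,
                 pixel_size_um = pixel_size_um), class = "cortex_path")
}

#' Build a cortex path from explicit coordinates
#'
#' Accepts a manually traced polyline (e.g. exported from an annotation
#' tool) instead of deriving one from a mask.
#'
#' @param vertices 2-column matrix of 0-based `(x, y)` coordinates from pole
#'   to pole.
#' @inheritParams extract_cortex_path
#' @return A `cortex_path` object.
#' @export
manual_cortex_path <- function(vertices, midplane, pixel_size_um = 1,
                               line_width_px = 5, sampling_step_px = 1) {
  if (nrow(vertices) < 2) stop_param("need at least two vertices")
  seg <- sqrt(rowSums(diff(vertices)^2))
  arc <- c(0, cumsum(seg))
  s_out <- seq(0, arc[length(arc)], by = sampling_step_px)
  v <- cbind(x = stats::approx(arc, vertices[, 1], xout = s_out)$y,
             y = stats::approx(arc, vertices[, 2], xout = s_out)$y)
  a <- midplane[1, ]; b <- midplane[2, ]
  u <- b - a; u <- u / sqrt(sum(u^2)); nvec <- c(-u[2], u[1])
  f <- (v[, 1] - a[1]) * nvec[1] + (v[, 2] - a[2]) * nvec[2]
  cross <- which(f[-length(f)] * f[-1] < 0 | f[-length(f)] == 0)
  if (length(cross) != 1) stop_param("midplane must cross the path exactly once")
  i <- cross
  frac <- if (f[i] == 0) 0 else f[i] / (f[i] - f[i + 1])
  s0 <- s_out[i] + frac * (s_out[i + 1] - s_out[i])
  structure(list(vertices = v, arc_pos_um = (s_out - s0) * pixel_size_um,
                 spacing_um = sampling_step_px * pixel_size_um,
                 cortex_length_um = arc[length(arc)] * pixel_size_um,
                 line_width_px = line_width_px,
                 sampling_step_px = sampling_step_px,
                 midplane = midplane, pixel_size_um = pixel_size_um),
            class = "cortex_path")
}

#' Sample image intensity along a cortex path
#'
#' At every path sample, `line_width_px` values are read at unit-pixel
#' offsets perpendicular to the local tangent (bilinear interpolation) and
#' averaged, reproducing a wide-line intensity profile. Positions are the
#' signed arc distances from the midplane crossing.
#'
#' @param image 2-D numeric matrix.
#' @param path a `cortex_path`.
#' @return A [linescan_profile()].
#' @export
sample_linescan <- function(image, path) {
  if (!inherits(path, "cortex_path")) stop_param("'path' must be a cortex_path")
  v <- path$vertices
  n <- nrow(v)
  # central-difference tangents
  tx <- c(v[2, 1] - v[1, 1], v[-(1:2), 1] - v[1:(n - 2), 1],
          v[n, 1] - v[n - 1, 1])
  ty <- c(v[2, 2] - v[1, 2], v[-(1:2), 2] - v[1:(n - 2), 2],
          v[n, 2] - v[n - 1, 2])
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  nx <- -ty / len; ny <- tx / len
  w <- path$line_width_px
  offsets <- seq(-(w - 1) / 2, (w - 1) / 2, by = 1)
  acc <- numeric(n)
  for (o in offsets)
    acc <- acc + interp_bilinear(image, v[, 1] + o * nx, v[, 2] + o * ny)
  linescan_profile(path$arc_pos_um, pmax(acc / length(offsets), 0),
                   path$spacing_um, path$cortex_length_um)
}

#' Peak-normalize a linescan profile
#'
#' @param profile a [linescan_profile()].
#' @return The profile with intensities divided by their maximum (so the
#'   maximum is exactly 1); positions unchanged. Idempotent.
#' @export
normalize_profile <- function(profile) {
  if (!inherits(profile, "linescan_profile"))
    stop_param("'profile' must be a linescan_profile")
  mx <- max(profile$intensity)
  if (mx <= 0) stop_param("cannot normalize an all-zero profile")
  out <- profile
  out$intensity <- profile$intensity / mx
  out$normalized <- TRUE
  out
}

#' Breadth of the equatorial peak at a fractional cutoff
#'
#' Counts the samples in the contiguous above-cutoff run that contains the
#' profile's global maximum and converts the count to microns. Above-cutoff
#' samples in any other run are excluded from the breadth and reported in
#' `n_pixels_excluded_outside_peak`. Ties for the global maximum are broken
#' toward the sample nearest position zero.
#'
#' @param profile a normalized [linescan_profile()].
#' @param cutoff_fraction cutoff as a fraction of the peak (default 0.5,
#'   i.e. full width at half maximum).
#' @return An object of class `breadth_result` with `breadth_um`,
#'   `breadth_pct_cortex`, `cutoff_fraction`, `n_pixels_counted` and
#'   `n_pixels_excluded_outside_peak`.
#' @export
measure_breadth <- function(profile, cutoff_fraction = 0.5) {
  if (!inherits(profile, "linescan_profile"))
    stop_param("'profile' must be a linescan_profile")
  if (!profile$normalized)
    stop_param("profile must be normalized (see normalize_profile)")
  y <- profile$intensity
  above <- y > cutoff_fraction
  if (!any(above)) {
    res <- list(breadth_um = 0, breadth_pct_cortex = 0,
                cutoff_fraction = cutoff_fraction, n_pixels_counted = 0L,
                n_pixels_excluded_outside_peak = 0L)
    return(structure(res, class = "breadth_result"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peak_candidates <- which(y == max(y))
  peak_i <- peak_candidates[which.min(abs(profile$position_um[peak_candidates]))]
  run <- which(starts <= peak_i & ends >= peak_i)
  n_in <- r$lengths[run]
  structure(list(
    breadth_um = n_in * profile$spacing_um,
    breadth_pct_cortex = 100 * n_in * profile$spacing_um /
      profile$cortex_length_um,
    cutoff_fraction = cutoff_fraction,
    n_pixels_counted = as.integer(n_in),
    n_pixels_excluded_outside_peak = as.integer(sum(above) - n_in)),
    class = "breadth_result")
}

#' @export
print.breadth_result <- function(x, ...) {
  cat(sprintf(
    "breadth: %.3g um (%.3g%% of cortex), %d px counted, %d excluded\n",
    x$breadth_um, x$breadth_pct_cortex, x$n_pixels_counted,
    x$n_pixels_excluded_outside_peak))
  invisible(x)
}

#' Analytic Gaussian-band linescan profile
#'
#' Generates a noise-free linescan of a Gaussian equatorial band:
#' `baseline + amplitude * exp(-pos^2 / (2 * sigma^2))`. With the default
#' zero baseline its breadth at the 50% cutoff equals the Gaussian full
#' width at half maximum, `2*sqrt(2*log(2)) * band_sigma_um`, which is the
#' closed-form oracle used to validate [measure_breadth()]. A non-zero
#' baseline emulates an unsubtracted cortical/cytosolic floor (see
#' [subtract_profile_baseline()]).
#'
#' @param band_sigma_um Gaussian band SD (um).
#' @param amplitude band amplitude above baseline.
#' @param baseline constant floor added to the whole profile.
#' @param spacing_um sample spacing (um).
#' @param half_length_um profile half-length (um).
#' @return A [linescan_profile()].
#' @export
gaussian_band_profile <- function(band_sigma_um, amplitude = 1, baseline = 0,
                                  spacing_um = 0.05, half_length_um = 12) {
  pos <- seq(-half_length_um, half_length_um, by = spacing_um)
  y <- baseline + amplitude * exp(-pos^2 / (2 * band_sigma_um^2))
  linescan_profile(pos, y, spacing_um, 2 * half_length_um)
}

#' Subtract the off-peak baseline of a linescan profile
#'
#' The cortex outside the equatorial band carries a residual floor (cytosol
#' and unenriched cortex). Removing it before peak normalization makes the
#' half-maximum cutoff refer to the band itself, so a Gaussian band of SD
#' sigma yields a breadth of `2*sqrt(2*log(2)) * sigma`.
#'
#' @param profile a [linescan_profile()].
#' @param method `"outer"` uses the median over the outer thirds of the
#'   path; `"min"` uses the profile minimum.
#' @param outer_fraction fraction of samples at each end treated as
#'   off-peak for `method = "outer"`.
#' @return The baseline-subtracted profile (clamped at 0), with the
#'   estimate in the `"profile_baseline"` attribute.
#' @export
subtract_profile_baseline <- function(profile, method = c("outer", "min"),
                                      outer_fraction = 1 / 3) {
  if (!inherits(profile, "linescan_profile"))
    stop_param("'profile' must be a linescan_profile")
  method <- match.arg(method)
  y <- profile$intensity
  n <- length(y)
  b <- if (method == "min") min(y) else {
    k <- max(1, floor(n * outer_fraction))
    stats::median(c(y[1:k], y[(n - k + 1):n]))
  }
  out <- profile
  out$intensity <- pmax(y - b, 0)
  out$normalized <- FALSE
  attr(out, "profile_baseline") <- b
  out
}
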