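# Synthetic dividing-cell movies.
#
# Geometry: the cell is the union of two circles of radius r whose centre
# separation encodes furrow ingression. The furrow (neck) width follows a
# piecewise-linear law: constant at 2r until furrow onset, then decreasing
# at the stated rate until full closure. The tagged-protein channel is
# cytosol + a cortical shell + a Gaussian equatorial band whose profile is
# a function of arc distance along the cortex, so the band's full width at
# half maximum is exactly 2*sqrt(2*log(2))*band_sigma_um. The camera chain
# is bleach -> Poisson shot noise on (exposure_gain x scene) -> additive
# Gaussian read noise -> rounding and clipping at zero.

furrow_width_law <- function(params, t_min) {
  w0 <- 2 * params$cell_radius_um
  pmax(w0 - params$ingression_rate_um_per_min *
         pmax(t_min - params$furrow_onset_min, 0), 0)
}

ang_diff <- function(a, b) abs(((a - b + pi) %% (2 * pi)) - pi)

# Expected (noise-free, unbleached) tag and chromatin scenes at one
# timepoint, at the cell midplane. Returns Y x X matrices plus geometry.
render_cell_frame <- function(params, t_min) {
  p <- params
  n <- p$img_size_px
  r <- p$cell_radius_um / p$pixel_size_um
  cx <- (n - 1) / 2; cy <- (n - 1) / 2
  w_um <- furrow_width_law(p, t_min)
  h <- (w_um / 2) / p$pixel_size_um          # neck half-width (px)
  h <- min(h, r)
  d <- 2 * sqrt(max(r^2 - h^2, 0))           # centre separation (px)
  x <- matrix(rep(0:(n - 1), each = n), n, n)   # [y+1, x+1] layout
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  d1 <- sqrt((x - (cx - d / 2))^2 + (y - cy)^2)
  d2 <- sqrt((x - (cx + d / 2))^2 + (y - cy)^2)
  in1 <- d1 <= r; in2 <- d2 <= r
  mask <- in1 | in2
  lens <- in1 & in2
  depth <- r - ifelse(lens, pmax(d1, d2), pmin(d1, d2))
  depth[!mask] <- -1
  thick <- p$cortex_thickness_um / p$pixel_size_um
  shell <- mask & depth <= thick
  interior <- mask & !shell

  # arc distance from the equator along the owning lobe's circle
  own1 <- (in1 & !in2) | (lens & d1 >= d2)
  theta <- ifelse(own1, atan2(y - cy, x - (cx - d / 2)),
                        atan2(y - cy, x - (cx + d / 2)))
  gam <- atan2(h, d / 2)                     # intersection angle, lobe 1
  ang1 <- ifelse(own1, gam, pi - gam)
  ang2 <- -ang1
  # arc distance measured at the shell centre-line, where the linescan path
  # runs, so the band FWHM along the path equals the closed form
  r_mid <- r - thick / 2
  arc_um <- r_mid * pmin(ang_diff(theta, ang1), ang_diff(theta, ang2)) *
    p$pixel_size_um

  band_on <- t_min >= p$accumulation_onset_min
  f <- rep(1, length(arc_um))
  if (band_on)
    f <- 1 + (p$cortical_ratio - 1) * exp(-arc_um^2 / (2 * p$band_sigma_um^2))
  shell_factor <- p$metaphase_cortical_ratio * f

  tag <- matrix(p$background_level, n, n)
  tag[interior] <- tag[interior] + p$cytosol_level
  tag[shell] <- tag[shell] + p$cytosol_level * shell_factor[shell]

  # chromatin: one metaphase plate before anaphase, two segregating masses
  # after (1.2 um/min separation speed, capped)
  chrom <- matrix(p$background_level, n, n)
  if (t_min < p$anaphase_onset_min) {
    sx <- 1 / p$pixel_size_um; sy <- 0.55 * r
    chrom <- chrom + p$chromatin_level *
      exp(-((x - cx)^2 / (2 * sx^2) + (y - cy)^2 / (2 * sy^2)))
  } else {
    sep <- min(1.2 * (t_min - p$anaphase_onset_min) / p$pixel_size_um, 1.4 * r)
    off <- max(d / 2, sep / 2)
    s <- 1.5 / p$pixel_size_um
    chrom <- chrom + p$chromatin_level *
      (exp(-((x - (cx - off))^2 + (y - cy)^2) / (2 * s^2)) +
       exp(-((x - (cx + off))^2 + (y - cy)^2) / (2 * s^2)))
  }

  boundary <- union_boundary_polyline(cx, cy, r, d, gam)
  list(tag = tag, chrom = chrom, mask = mask, width_um = w_um,
       centers = cbind(c(cx - d / 2, cx + d / 2), c(cy, cy)),
       boundary = boundary, midplane = rbind(c(cx, 0), c(cx, n - 1)))
}

# Ordered polyline (0-based x, y) of the two-lobed cell outline, starting at
# the top neck point and travelling counter-clockwise around the left lobe.
union_boundary_polyline <- function(cx, cy, r, d, gam, step_deg = 2) {
  st <- step_deg * pi / 180
  a1 <- seq(gam, 2 * pi - gam, by = st)               # left lobe outer arc
  a2 <- seq(pi + gam, 3 * pi - gam, by = st)          # right lobe outer arc
  p1 <- cbind((cx - d / 2) + r * cos(a1), cy + r * sin(a1))
  p2 <- cbind((cx + d / 2) + r * cos(a2), cy + r * sin(a2))
  rbind(p1, p2)
}

# Apply the camera chain to an expected-photon scene.
apply_camera <- function(lambda, exposure_gain, read_noise_sd) {
  counts <- stats::rpois(length(lambda), exposure_gain * as.vector(lambda))
  if (read_noise_sd > 0)
    counts <- counts + stats::rnorm(length(lambda), 0, read_noise_sd)
  array(pmax(round(counts), 0), dim = dim(lambda))
}

# z attenuation of the cell signal: Gaussian envelope (SD = half the cell
# radius) around the central slice; slices are 1 um apart, matching a
# 9-slice 1-um acquisition. Background is constant in z.
z_envelope <- function(params) {
  z <- seq_len(params$n_z)
  zmid <- (params$n_z + 1) / 2
  exp(-((z - zmid) * 1.0)^2 / (2 * (params$cell_radius_um / 2)^2))
}

# Render the full expected (noise-free) movie, bleach included.
# Returns a T x Z x C x Y x X array; channel 1 = tag, 2 = chromatin.
render_movie_scene <- function(params) {
  p <- params
  n <- p$img_size_px
  scene <- array(0, dim = c(p$n_frames, p$n_z, 2, n, n))
  env <- z_envelope(p)
  frames <- vector("list", p$n_frames)
  for (t in seq_len(p$n_frames)) {
    t_min <- (t - 1) * p$frame_interval_min
    fr <- render_cell_frame(p, t_min)
    frames[[t]] <- fr
    bleach <- (1 - p$bleach_rate)^(t - 1)
    for (z in seq_len(p$n_z)) {
      scene[t, z, 1, , ] <- bleach *
        (p$background_level + (fr$tag - p$background_level) * env[z])
      scene[t, z, 2, , ] <- bleach *
        (p$background_level + (fr$chrom - p$background_level) * env[z])
    }
  }
  list(scene = scene, frames = frames)
}

#' Simulate a timelapse movie of a dividing cell
#'
#' Renders a two-lobed cell with a cortically enriched tagged protein and a
#' chromatin channel, applies photobleaching, Poisson shot noise and
#' Gaussian read noise, and returns the stack together with a ground-truth
#' record of every generative quantity.
#'
#' @param params a [cell_sim_params()] object.
#' @param seed integer seed; identical `(params, seed)` give bit-identical
#'   stacks.
#' @return A list with elements:
#'   \describe{
#'     \item{stack}{a [timelapse_stack()] with channels `tag` and
#'       `chromatin`.}
#'     \item{truth}{a `movie_truth` list: per-frame `furrow_width_um`, the
#'       analytic band FWHM (`2*sqrt(2*log(2)) * band_sigma_um`), the true
#'       cortical ratio, anaphase/accumulation/furrow onset frames, the
#'       rule-based onset and completion frames evaluated on the exact width
#'       trace (see [ingression_duration()]), per-frame cell masks, cortex
#'       outlines and the midplane line.}
#'   }
#' @export
simulate_division_movie <- function(params = cell_sim_params(), seed = 1) {
  if (!inherits(params, "cell_sim_params"))
    stop_param("'params' must come from cell_sim_params()")
  p <- params
  rs <- render_movie_scene(p)
  vox <- with_seed(derive_seed(seed, 1),
                   apply_camera(rs$scene, p$exposure_gain, p$read_noise_sd))
  stack <- timelapse_stack(vox, p$pixel_size_um, p$frame_interval_min,
                           c(tag = 1L, chromatin = 2L))
  t_min <- (seq_len(p$n_frames) - 1) * p$frame_interval_min
  width <- furrow_width_law(p, t_min)
  idx <- which(t_min >= p$anaphase_onset_min)
  anaphase_frame <- if (length(idx)) idx[1] else p$n_frames
  rule <- ingression_rule_frames(width, anaphase_frame)
  truth <- structure(list(
    furrow_width_um = width,
    band_fwhm_um = 2 * sqrt(2 * log(2)) * p$band_sigma_um,
    cortical_ratio = p$cortical_ratio,
    anaphase_onset_frame = anaphase_frame,
    accumulation_onset_frame =
      suppressWarnings(min(which(t_min >= p$accumulation_onset_min),
                           p$n_frames + 1L)),
    furrow_onset_frame = suppressWarnings(min(which(width < width[1]),
                                              p$n_frames + 1L)),
    closure_frame = if (any(width == 0)) min(which(width == 0)) else NA_integer_,
    rule_onset_frame = rule$onset, rule_completion_frame = rule$completion,
    rule_duration_min = rule$duration_frames * p$frame_interval_min,
    masks = lapply(rs$frames, `[[`, "mask"),
    cortex_paths = lapply(rs$frames, `[[`, "boundary"),
    midplane = rs$frames[[1]]$midplane,
    params = unclass(p)), class = "movie_truth")
  list(stack = stack, truth = truth)
}

#' Simulate a single metaphase cell image
#'
#' Renders one 2-D frame of a round metaphase cell whose whole cortex shell
#' is uniformly enriched `cortical_ratio`-fold over the cytosol (no
#' equatorial band), for testing cortical/cytosolic ratio measurements.
#'
#' @param params a [cell_sim_params()]; `cortical_ratio` is used as the
#'   uniform shell enrichment.
#' @param seed integer seed.
#' @return A list with `image` (Y x X counts), `mask`, suggested `poles`
#'   (0-based x,y on the boundary), a central `cytosol_roi`, a corner
#'   `background_roi`, and the generating parameters.
#' @export
simulate_metaphase_cell <- function(params = cell_sim_params(), seed = 1) {
  p <- params
  p$metaphase_cortical_ratio <- p$cortical_ratio
  p$accumulation_onset_min <- Inf      # no equatorial band
  p$furrow_onset_min <- Inf            # round cell
  fr <- render_cell_frame(p, 0)
  img <- with_seed(derive_seed(seed, 2),
                   apply_camera(fr$tag, p$exposure_gain, p$read_noise_sd))
  n <- p$img_size_px
  r <- p$cell_radius_um / p$pixel_size_um
  cx <- (n - 1) / 2
  rr <- 0.3 * r
  list(image = matrix(img, n, n), mask = fr$mask,
       poles = rbind(c(cx - r, cx), c(cx + r, cx)),
       cytosol_roi = roi_rect(round(cx - rr), round(cx - rr),
                              round(2 * rr), round(2 * rr)),
       background_roi = roi_rect(2, 2, 8, 8),
       params = unclass(p))
}

#' Simulate a matched low/high-exposure image pair
#'
#' Renders one underlying noiseless scene and images it twice with different
#' exposure settings. The two stacks are pixel-registered and differ only in
#' photon-collection gain and read noise, emulating matched training pairs
#' for image restoration.
#'
#' @param params a [cell_sim_params()] describing the scene (`exposure_gain`
#'   and `read_noise_sd` in `params` are ignored).
#' @param low,high lists with elements `exposure_gain` and `read_noise_sd`.
#' @param seed integer seed.
#' @param frames which timepoints to render (default all).
#' @return A list with `low` and `high` [timelapse_stack()]s, the noiseless
#'   `scene` array and the per-frame geometry `truth`.
#' @export
simulate_exposure_pair <- function(params = cell_sim_params(),
                                   low = list(exposure_gain = 1,
                                              read_noise_sd = 2),
                                   high = list(exposure_gain = 10,
                                               read_noise_sd = 2),
                                   seed = 1, frames = NULL) {
  p <- params
  for (s in list(low, high)) {
    check_positive(s$exposure_gain, "exposure_gain")
    check_positive(s$read_noise_sd, "read_noise_sd", strict = FALSE)
  }
  if (!is.null(frames)) {
    p$n_frames <- length(frames)
  }
  rs <- render_movie_scene(if (is.null(frames)) p else {
    q <- p; q$n_frames <- max(frames); q
  })
  scene <- rs$scene
  if (!is.null(frames)) scene <- scene[frames, , , , , drop = FALSE]
  mk <- function(settings, k) {
    vox <- with_seed(derive_seed(seed, k),
                     apply_camera(scene, settings$exposure_gain,
                                  settings$read_noise_sd))
    timelapse_stack(vox, p$pixel_size_um, p$frame_interval_min,
                    c(tag = 1L, chromatin = 2L))
  }
  list(low = mk(low, 3), high = mk(high, 4), scene = scene,
       truth = list(frames = if (is.null(frames)) rs$frames else rs$frames[frames]))
}
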