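# Synthetic 96-well colony montages: per-well images with a dark circular
# well edge, a gentle background ramp, Gaussian-profile colony blobs, small
# debris specks and Gaussian pixel noise, plus a ground-truth table.

well_ids <- function(n) {
  ids <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  if (n > length(ids)) c(ids, paste0("W", seq_len(n - length(ids)))) else ids[seq_len(n)]
}

render_well <- function(p, n_colonies, n_debris, rng_draws) {
  sz <- 2 * ceiling(p$well_radius_px * 1.1) + 1
  c0 <- (sz - 1) / 2
  x <- matrix(rep(0:(sz - 1), each = sz), sz, sz)
  y <- matrix(rep(0:(sz - 1), times = sz), sz, sz)
  r <- sqrt((x - c0)^2 + (y - c0)^2)
  img <- p$background_level +
    p$background_gradient * ((x + y) / (2 * sz) - 0.5)
  # dark well edge: ring at the well radius and darkness outside it
  edge <- r >= 0.95 * p$well_radius_px
  img[edge] <- img[edge] * (1 - p$edge_darkening)
  # objects are placed with a minimum pairwise separation so that distinct
  # truth objects remain distinct after blurring (overlapping colonies would
  # be a single object by construction)
  placed <- matrix(numeric(0), ncol = 3)
  place <- function(rad, max_r_frac) {
    for (try in 1:200) {
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- stats::runif(1, 0, max_r_frac * p$well_radius_px)
      cx <- c0 + rr * cos(ang); cy <- c0 + rr * sin(ang)
      if (nrow(placed) == 0) break
      d <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
      if (all(d > placed[, 3] + rad + 10)) break
    }
    placed <<- rbind(placed, c(cx, cy, rad))
    c(cx, cy)
  }
  for (i in seq_len(n_colonies)) {
    rad <- stats::runif(1, p$colony_radius_range_px[1],
                        p$colony_radius_range_px[2])
    ctr <- place(rad, 0.55)
    img <- img + p$colony_amplitude *
      exp(-((x - ctr[1])^2 + (y - ctr[2])^2) / (2 * (rad / 2)^2))
  }
  for (i in seq_len(n_debris)) {
    ctr <- place(p$debris_size_px, 0.7)
    img <- img + 1.5 * p$colony_amplitude *
      exp(-((x - ctr[1])^2 + (y - ctr[2])^2) /
            (2 * (p$debris_size_px / 1.5)^2))
  }
  if (p$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, p$noise_sd)
  list(image = pmax(img, 0), center = c(c0, c0),
       radius = p$well_radius_px, colonies = placed)
}

#' Simulate a 96-well plate of colony images
#'
#' Draws a colony count per well from the requested distribution, renders
#' each well with edge, background gradient, colonies, optional debris and
#' noise, and returns the images together with a per-well truth table.
#'
#' @param params a [plate_sim_params()].
#' @param seed integer seed.
#' @return A list with:
#'   \describe{
#'     \item{wells}{named list of `well_image` objects (`well_id`, `image`,
#'       `well_center_px`, `well_radius_px`).}
#'     \item{truth}{data frame with `well_id`, `n_colonies`, `n_debris` and
#'       the truth call under the screening rule (`positive` for exactly one
#'       colony and no debris, `excluded` for multiple colonies or debris,
#'       otherwise `negative`).}
#'   }
#' @export
simulate_plate_montage <- function(params = plate_sim_params(), seed = 1) {
  if (!inherits(params, "plate_sim_params"))
    stop_param("'params' must come from plate_sim_params()")
  p <- params
  ids <- well_ids(p$n_wells)
  with_seed(derive_seed(seed, 5), {
    counts <- as.integer(names(p$colony_count_distribution))[
      sample.int(length(p$colony_count_distribution), p$n_wells,
                 replace = TRUE, prob = p$colony_count_distribution)]
    debris <- stats::rbinom(p$n_wells, 1, p$debris_probability)
    wells <- vector("list", p$n_wells)
    for (i in seq_len(p$n_wells)) {
      rw <- render_well(p, counts[i], debris[i], NULL)
      wells[[i]] <- structure(list(well_id = ids[i], image = rw$image,
                                   well_center_px = rw$center,
                                   well_radius_px = rw$radius),
                              class = "well_image")
    }
    names(wells) <- ids
    truth <- data.frame(well_id = ids, n_colonies = counts,
                        n_debris = debris, stringsAsFactors = FALSE)
    truth$call <- ifelse(truth$n_colonies == 1 & truth$n_debris == 0,
                         "positive",
                         ifelse(truth$n_colonies > 1 | truth$n_debris > 0,
                                "excluded", "negative"))
    list(wells = wells, truth = truth)
  })
}
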