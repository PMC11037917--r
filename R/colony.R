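# Automated colony screening of 96-well plate images: crop the well edge,
# subtract background, blur, threshold high-contrast regions, count objects
# and call each well positive / negative / excluded.

#' Crop the well edge from a well image
#'
#' Pixels outside `margin_fraction` times the well radius are masked out of
#' all downstream statistics, removing the dark well edge.
#'
#' @param well a `well_image` (see [simulate_plate_montage()]) or a plain
#'   matrix together with `center` and `radius`.
#' @param margin_fraction fraction of the well radius retained.
#' @param center,radius well geometry when `well` is a plain matrix
#'   (0-based center).
#' @return A list with `image` and logical `mask` of retained pixels.
#' @export
crop_well <- function(well, margin_fraction = 0.9, center = NULL,
                      radius = NULL) {
  if (inherits(well, "well_image")) {
    img <- well$image; center <- well$well_center_px
    radius <- well$well_radius_px
  } else img <- well
  if (is.null(center) || is.null(radius))
    stop_param("well geometry (center, radius) required")
  if (margin_fraction <= 0 || margin_fraction > 1)
    stop_param("'margin_fraction' must lie in (0, 1]")
  ny <- nrow(img); nx <- ncol(img)
  if (center[1] < 0 || center[1] >= nx || center[2] < 0 || center[2] >= ny ||
      radius <= 0)
    stop_param("well geometry out of bounds")
  x <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  y <- matrix(rep(0:(ny - 1), times = nx), ny, nx)
  mask <- sqrt((x - center[1])^2 + (y - center[2])^2) <=
    margin_fraction * radius
  list(image = img, mask = mask)
}

#' Detect colonies in a cropped well
#'
#' Pipeline: subtract the median of the masked pixels, Gaussian blur,
#' threshold at `mean + threshold_k * SD` of the masked blurred image, and
#' label connected components. Components of at least `min_colony_area_px`
#' are colonies; smaller components of at least `min_object_area_px` are
#' debris; anything smaller is ignored as noise.
#'
#' @param cropped list with `image` and `mask` from [crop_well()].
#' @param blur_sigma_px Gaussian blur SD (pixels).
#' @param threshold_k number of SDs above the mean for the threshold.
#' @param min_colony_area_px minimum connected area of a colony.
#' @param min_object_area_px minimum area counted as an object at all.
#' @return An object of class `colony_detection`: `colony_count`,
#'   `debris_count`, a label matrix, per-object areas and outlines
#'   (0-based x, y contours) for QC overlay, and the threshold used.
#' @export
detect_colonies <- function(cropped, blur_sigma_px = 4, threshold_k = 3,
                            min_colony_area_px = 300,
                            min_object_area_px = 15) {
  img <- cropped$image; mask <- cropped$mask
  if (!any(mask)) stop_param("well mask is empty")
  bg <- stats::median(img[mask])
  res <- pmax(img - bg, 0)
  res[!mask] <- 0
  blur <- EBImage::gblur(res, sigma = blur_sigma_px)
  mv <- mean(blur[mask]); sv <- stats::sd(blur[mask])
  thr <- mv + threshold_k * sv
  bin <- blur > thr & mask
  lab <- EBImage::bwlabel(bin)
  n_obj <- max(lab)
  areas <- if (n_obj > 0) tabulate(lab[lab > 0], nbins = n_obj) else integer(0)
  keep <- which(areas >= min_object_area_px)
  colony_ids <- keep[areas[keep] >= min_colony_area_px]
  debris_ids <- keep[areas[keep] < min_colony_area_px]
  outlines <- lapply(keep, function(i) {
    oc <- EBImage::ocontour(lab == i)[[1]]
    cbind(x = oc[, 2], y = oc[, 1])
  })
  names(outlines) <- as.character(keep)
  structure(list(colony_count = length(colony_ids),
                 debris_count = length(debris_ids),
                 labels = lab, areas = areas,
                 colony_ids = colony_ids, debris_ids = debris_ids,
                 outlines = outlines, threshold = thr,
                 background = bg),
            class = "colony_detection")
}

#' Call a well from its detected objects
#'
#' A well is `positive` when it contains exactly one colony and no more
#' debris than tolerated, `excluded` when it contains multiple colonies or
#' too much debris, and `negative` otherwise.
#'
#' @param objects a `colony_detection` from [detect_colonies()].
#' @param well_id well identifier carried into the record.
#' @param debris_tolerance maximum debris count that does not exclude a
#'   well (default 0: any debris excludes).
#' @return An object of class `well_record`: `well_id`, `colony_count`,
#'   `debris_count`, `call` and the QC `outlines`.
#' @export
call_well <- function(objects, well_id = NA_character_,
                      debris_tolerance = 0) {
  nc <- objects$colony_count; nd <- objects$debris_count
  call <- if (nc > 1 || nd > debris_tolerance) "excluded"
          else if (nc == 1) "positive" else "negative"
  structure(list(well_id = well_id, colony_count = nc, debris_count = nd,
                 call = call, outlines = objects$outlines),
            class = "well_record")
}

#' @export
print.well_record <- function(x, ...) {
  cat(sprintf("well %s: %d colonies, %d debris -> %s\n",
              x$well_id, x$colony_count, x$debris_count, x$call))
  invisible(x)
}

#' Screen a plate of well images
#'
#' Runs [crop_well()], [detect_colonies()] and [call_well()] on every well
#' and summarizes the plate, reporting the clonal recovery fraction
#' (positive wells over total wells).
#'
#' @param wells list of `well_image` objects with unique `well_id`s.
#' @param margin_fraction passed to [crop_well()].
#' @param blur_sigma_px,threshold_k,min_colony_area_px,min_object_area_px
#'   passed to [detect_colonies()].
#' @param debris_tolerance passed to [call_well()].
#' @return An object of class `plate_screen`: a `records` data frame (one
#'   row per well), the per-well `outlines`, and a `summary` list with
#'   counts per call and `recovery_fraction`.
#' @export
screen_plate <- function(wells, margin_fraction = 0.9, blur_sigma_px = 4,
                         threshold_k = 3, min_colony_area_px = 300,
                         min_object_area_px = 15, debris_tolerance = 0) {
  if (length(wells) < 1) stop_param("need at least one well")
  ids <- vapply(wells, `[[`, "", "well_id")
  if (anyDuplicated(ids)) stop_param("duplicate well_ids")
  recs <- lapply(wells, function(w) {
    det <- detect_colonies(crop_well(w, margin_fraction),
                           blur_sigma_px, threshold_k,
                           min_colony_area_px, min_object_area_px)
    call_well(det, w$well_id, debris_tolerance)
  })
  df <- data.frame(well_id = ids,
                   colony_count = vapply(recs, `[[`, 0L, "colony_count"),
                   debris_count = vapply(recs, `[[`, 0L, "debris_count"),
                   call = vapply(recs, `[[`, "", "call"),
                   stringsAsFactors = FALSE)
  counts <- table(factor(df$call, levels = c("positive", "negative",
                                             "excluded")))
  structure(list(records = df,
                 outlines = lapply(recs, `[[`, "outlines"),
                 summary = list(n_wells = length(wells),
                                n_positive = unname(counts["positive"]),
                                n_negative = unname(counts["negative"]),
                                n_excluded = unname(counts["excluded"]),
                                recovery_fraction =
                                  unname(counts["positive"]) / length(wells))),
            class = "plate_screen")
}

#' @export
print.plate_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "plate_screen: %d wells -> %d positive, %d negative, %d excluded\n",
    s$n_wells, s$n_positive, s$n_negative, s$n_excluded))
  cat(sprintf("  clonal recovery: %.1f%%\n", 100 * s$recovery_fraction))
  invisible(x)
}
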