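#' Signal-to-noise ratio of matched ROIs
#'
#' Computes `SNR = (mean signal - mean background) / signal SD`, with the
#' signal SD taken as the sample standard deviation (n - 1 denominator) of
#' the signal ROI. The same ROI pair can be reused across matched
#' low/high-exposure images of the same scene.
#'
#' @param image 2-D numeric matrix.
#' @param signal_roi ROI over homogeneous signal (>= 2 pixels); see
#'   [roi_rect()].
#' @param background_roi ROI over background.
#' @return An object of class `snr_result` with `mean_signal`,
#'   `mean_background`, `signal_sd` and `snr`.
#' @export
measure_snr <- function(image, signal_roi, background_roi) {
  s <- roi_values(image, signal_roi, "signal_roi")
  b <- roi_values(image, background_roi, "background_roi")
  if (length(s) < 2) stop_param("signal ROI needs at least 2 pixels")
  sd_s <- stats::sd(s)
  if (sd_s == 0) stop_param("signal SD is zero; SNR undefined")
  structure(list(mean_signal = mean(s), mean_background = mean(b),
                 signal_sd = sd_s,
                 snr = (mean(s) - mean(b)) / sd_s),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("SNR = (%.4g - %.4g) / %.4g = %.4g\n",
              x$mean_signal, x$mean_background, x$signal_sd, x$snr))
  invisible(x)
}

#' Cortical to cytosolic intensity ratio
#'
#' The cortical mean is the average of the full cortex linescan; the
#' cytosolic mean is the average over a user-drawn cytosol ROI.
#'
#' @param image 2-D numeric matrix (background-subtracted).
#' @param path a `cortex_path` (see [extract_cortex_path()]).
#' @param cytosol_roi ROI inside the cell, away from the cortex.
#' @return An object of class `cort_cyto_ratio` with `cortical_mean`,
#'   `cytosolic_mean` and `ratio`.
#' @export
cortical_cytosolic_ratio <- function(image, path, cytosol_roi) {
  prof <- sample_linescan(image, path)
  cyto_idx <- roi_index(image, cytosol_roi, "cytosol_roi")
  cyto <- mean(image[cyto_idx])
  if (cyto == 0) stop_param("cytosolic mean is zero; ratio undefined")
  # warn if the ROI encroaches on the sampled cortex band
  ny <- nrow(image)
  ri <- cyto_idx - 1
  rx <- ri %/% ny; ry <- ri %% ny
  v <- path$vertices
  halfw <- path$line_width_px / 2
  mind <- min(sqrt(outer(rx, v[, 1], `-`)^2 + outer(ry, v[, 2], `-`)^2))
  if (mind < halfw)
    warning("cytosol ROI overlaps the cortex sampling band")
  structure(list(cortical_mean = mean(prof$intensity),
                 cytosolic_mean = cyto,
                 ratio = mean(prof$intensity) / cyto),
            class = "cort_cyto_ratio")
}

#' @export
print.cort_cyto_ratio <- function(x, ...) {
  cat(sprintf("cortical/cytosolic ratio = %.4g / %.4g = %.4g\n",
              x$cortical_mean, x$cytosolic_mean, x$ratio))
  invisible(x)
}
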