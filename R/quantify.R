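# End-to-end cytokinesis quantification of a timelapse stack: per-frame
# preprocessing (central-z projection, background subtraction), cell
# segmentation, furrow width trace, cortical linescans and breadth, and
# equatorial accumulation timing.

# Poles of a (possibly two-lobed) mask: extreme points along the pole axis.
mask_poles <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)       # (row = y+1, col = x+1)
  xs <- idx[, 2] - 1; ys <- idx[, 1] - 1
  i1 <- which.min(xs); i2 <- which.max(xs)
  rbind(c(xs[i1], ys[i1]), c(xs[i2], ys[i2]))
}

#' Quantify cytokinesis in a timelapse stack
#'
#' Runs the full linescan pipeline on the tag channel: average projection of
#' the two central z-slices, background subtraction, bleach correction,
#' per-frame cell segmentation, furrow width trace with onset/completion
#' annotation, pole-to-pole cortical linescans (baseline-subtracted and
#' peak-normalized) with breadth at the half-maximum cutoff, and equatorial
#' accumulation onset relative to anaphase.
#'
#' @param stack a [timelapse_stack()] with a `tag` channel.
#' @param anaphase_onset_frame 1-based frame of anaphase onset (supplied by
#'   the user; chromatin-based detection is out of scope).
#' @param background_roi optional background ROI reused on every frame;
#'   default is the per-frame 5th percentile.
#' @param z_pair two central z-slices to project (default: the middle pair).
#' @param inset_px inward offset of the cortex path from the mask boundary.
#' @param line_width_px linescan width (default 5).
#' @param breadth_frames frames at which breadth is measured (default: the
#'   annotated furrow onset frame, matching measurement at furrow
#'   initiation; all frames when `"all"`).
#' @param bleach_correct apply ratio bleach correction before measuring.
#' @param ... onset/completion rule settings passed to
#'   [furrow_width_trace()].
#' @return An object of class `cytokinesis_quant`: the `trace`
#'   (`ingression_trace`), `profiles` (per-frame normalized linescans),
#'   a `breadth` data frame, the `accumulation` result, and a tidy
#'   `results` data frame (one row per frame).
#' @export
quantify_movie <- function(stack, anaphase_onset_frame,
                           background_roi = NULL, z_pair = NULL,
                           inset_px = 3, line_width_px = 5,
                           breadth_frames = NULL, bleach_correct = TRUE,
                           ...) {
  d <- dim(stack$voxels)
  n_frames <- d[1]
  if (anaphase_onset_frame < 1 || anaphase_onset_frame > n_frames)
    stop_param("'anaphase_onset_frame' outside the movie")
  work <- if (bleach_correct) correct_bleach(stack) else stack
  imgs <- vector("list", n_frames)
  masks <- vector("list", n_frames)
  bgs <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    img <- project_central_z(work, t, z_pair)
    img <- subtract_background(img, roi = background_roi)
    bgs[t] <- attr(img, "background")
    imgs[[t]] <- img
    masks[[t]] <- segment_cell(img, subtract = FALSE)
  }
  trace <- furrow_width_trace(masks, stack$pixel_size_um,
                              stack$frame_interval_min,
                              anaphase_onset_frame, ...)
  profiles <- vector("list", n_frames)
  raw_profiles <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    prof <- tryCatch({
      poles <- mask_poles(masks[[t]])
      path <- extract_cortex_path(masks[[t]], poles[1, ], poles[2, ],
                                  line_width_px = line_width_px,
                                  pixel_size_um = stack$pixel_size_um,
                                  inset_px = inset_px)
      sample_linescan(imgs[[t]], path)
    }, error = function(e) NULL)
    raw_profiles[[t]] <- prof
    profiles[[t]] <- if (is.null(prof)) NULL else
      normalize_profile(subtract_profile_baseline(prof))
  }
  if (is.null(breadth_frames))
    breadth_frames <- if (!is.na(trace$furrow_onset_frame))
      trace$furrow_onset_frame else integer(0)
  else if (identical(breadth_frames, "all"))
    breadth_frames <- seq_len(n_frames)
  breadth <- do.call(rbind, lapply(breadth_frames, function(t) {
    if (is.null(profiles[[t]])) return(NULL)
    b <- measure_breadth(profiles[[t]])
    data.frame(frame = t, breadth_um = b$breadth_um,
               breadth_pct_cortex = b$breadth_pct_cortex,
               n_pixels_counted = b$n_pixels_counted,
               n_pixels_excluded = b$n_pixels_excluded_outside_peak)
  }))
  post <- raw_profiles[anaphase_onset_frame:n_frames]
  keep <- !vapply(post, is.null, TRUE)
  accumulation <- if (sum(keep) >= 2) {
    # profiles are evenly spaced in time starting at anaphase onset
    accumulation_onset(post[keep], stack$frame_interval_min)
  } else NULL
  results <- data.frame(
    frame = seq_len(n_frames),
    time_min = (seq_len(n_frames) - 1) * stack$frame_interval_min,
    furrow_width_um = trace$furrow_width_um,
    background = bgs)
  structure(list(trace = trace, profiles = profiles,
                 raw_profiles = raw_profiles, breadth = breadth,
                 accumulation = accumulation, results = results,
                 anaphase_onset_frame = anaphase_onset_frame),
            class = "cytokinesis_quant")
}

#' @export
print.cytokinesis_quant <- function(x, ...) {
  cat("cytokinesis_quant\n")
  print(x$trace)
  if (!is.null(x$breadth) && nrow(x$breadth))
    cat(sprintf("  breadth at frame %d: %.3g um (%.3g%% of cortex)\n",
                x$breadth$frame[1], x$breadth$breadth_um[1],
                x$breadth$breadth_pct_cortex[1]))
  if (!is.null(x$accumulation)) print(x$accumulation)
  invisible(x)
}
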