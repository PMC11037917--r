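# Furrow ingression kinetics: per-frame furrow width from cell masks, and
# the onset/completion rule that converts a width trace into an ingression
# duration. The operational rule (relative-width onset threshold, absolute
# closure width, persistence requirement) is configurable; defaults are
# documented inventions.

# Shared onset/completion rule on a width trace. Returns 1-based frames, or
# NA when the rule is never satisfied within the trace.
ingression_rule_frames <- function(width_um, anaphase_onset_frame,
                                   onset_threshold_fraction = 0.95,
                                   completion_width_um = 1.0,
                                   persistence_frames = 2) {
  n <- length(width_um)
  a <- max(1L, as.integer(anaphase_onset_frame))
  pre <- stats::median(width_um[seq_len(a)])
  thr <- onset_threshold_fraction * pre
  onset <- NA_integer_
  for (t in a:n) {
    hi <- min(t + persistence_frames - 1, n)
    if (hi - t + 1 < persistence_frames) break
    if (all(width_um[t:hi] <= thr)) { onset <- t; break }
  }
  completion <- NA_integer_
  idx <- which(width_um <= completion_width_um)
  idx <- idx[idx >= a]
  if (length(idx)) completion <- idx[1]
  dur <- if (!is.na(onset) && !is.na(completion)) completion - onset
         else NA_integer_
  list(onset = onset, completion = completion, duration_frames = dur,
       pre_anaphase_width_um = pre)
}

#' Furrow width trace from per-frame cell masks
#'
#' The furrow width at each frame is the minimal cell width along the
#' equatorial axis: mask columns (perpendicular to the pole-pole axis) are
#' measured in a small window around the mask centroid, and the smallest
#' pixel count is converted to microns. Onset and completion are annotated
#' with the rule described in [ingression_duration()].
#'
#' @param masks list of logical Y x X masks, one per frame.
#' @param pixel_size_um pixel size (um).
#' @param frame_interval_min frame interval (min).
#' @param anaphase_onset_frame 1-based frame of anaphase onset.
#' @param pole_axis `"x"` if the poles separate along image columns.
#' @param centroid_window_px half-width of the column window around the
#'   centroid searched for the minimal width.
#' @param onset_threshold_fraction onset rule: first frame at or below this
#'   fraction of the median pre-anaphase width, sustained.
#' @param completion_width_um completion rule: first frame at or below this
#'   width.
#' @param persistence_frames number of consecutive frames the onset
#'   condition must hold.
#' @return An object of class `ingression_trace` with `furrow_width_um`,
#'   the annotated frames, and `duration_min` (NA when incomplete).
#' @export
furrow_width_trace <- function(masks, pixel_size_um, frame_interval_min,
                               anaphase_onset_frame,
                               pole_axis = c("x", "y"),
                               centroid_window_px = 2,
                               onset_threshold_fraction = 0.95,
                               completion_width_um = 1.0,
                               persistence_frames = 2) {
  pole_axis <- match.arg(pole_axis)
  width <- vapply(seq_along(masks), function(t) {
    m <- masks[[t]]
    if (!any(m)) stop_param(sprintf("empty mask at frame %d", t))
    if (pole_axis == "y") m <- t(m)
    counts <- colSums(m)                       # width per column (pixels)
    cols <- which(counts > 0)
    cx <- sum(counts * seq_along(counts)) / sum(counts)   # centroid column
    win <- cols[abs(cols - cx) <= centroid_window_px]
    if (!length(win)) return(0)                # lobes already separated
    min(counts[win]) * pixel_size_um
  }, numeric(1))
  rule <- ingression_rule_frames(width, anaphase_onset_frame,
                                 onset_threshold_fraction,
                                 completion_width_um, persistence_frames)
  structure(list(furrow_width_um = width,
                 anaphase_onset_frame = as.integer(anaphase_onset_frame),
                 furrow_onset_frame = rule$onset,
                 completion_frame = rule$completion,
                 duration_min = if (is.na(rule$duration_frames)) NA_real_
                                else rule$duration_frames * frame_interval_min,
                 pre_anaphase_width_um = rule$pre_anaphase_width_um,
                 frame_interval_min = frame_interval_min,
                 onset_threshold_fraction = onset_threshold_fraction,
                 completion_width_um = completion_width_um,
                 persistence_frames = persistence_frames),
            class = "ingression_trace")
}

#' Build an ingression trace from an explicit width series
#'
#' @param width_um numeric vector of furrow widths (um) per frame.
#' @inheritParams furrow_width_trace
#' @return An `ingression_trace`.
#' @export
ingression_trace <- function(width_um, frame_interval_min = 1,
                             anaphase_onset_frame = 1,
                             onset_threshold_fraction = 0.95,
                             completion_width_um = 1.0,
                             persistence_frames = 2) {
  rule <- ingression_rule_frames(width_um, anaphase_onset_frame,
                                 onset_threshold_fraction,
                                 completion_width_um, persistence_frames)
  structure(list(furrow_width_um = width_um,
                 anaphase_onset_frame = as.integer(anaphase_onset_frame),
                 furrow_onset_frame = rule$onset,
                 completion_frame = rule$completion,
                 duration_min = if (is.na(rule$duration_frames)) NA_real_
                                else rule$duration_frames * frame_interval_min,
                 pre_anaphase_width_um = rule$pre_anaphase_width_um,
                 frame_interval_min = frame_interval_min,
                 onset_threshold_fraction = onset_threshold_fraction,
                 completion_width_um = completion_width_um,
                 persistence_frames = persistence_frames),
            class = "ingression_trace")
}

#' @export
print.ingression_trace <- function(x, ...) {
  cat(sprintf("ingression_trace: %d frames, pre-anaphase width %.3g um\n",
              length(x$furrow_width_um), x$pre_anaphase_width_um))
  if (is.na(x$duration_min)) cat("  ingression incomplete within the movie\n")
  else cat(sprintf("  onset frame %d, completion frame %d, duration %.3g min\n",
                   x$furrow_onset_frame, x$completion_frame, x$duration_min))
  invisible(x)
}

#' @method plot ingression_trace
#' @export
plot.ingression_trace <- function(x, ...) {
  t_min <- (seq_along(x$furrow_width_um) - 1) * x$frame_interval_min
  graphics::plot(t_min, x$furrow_width_um, type = "b",
                 xlab = "time (min)", ylab = "furrow width (um)", ...)
  if (!is.na(x$furrow_onset_frame))
    graphics::abline(v = t_min[x$furrow_onset_frame], lty = 2)
  if (!is.na(x$completion_frame))
    graphics::abline(v = t_min[x$completion_frame], lty = 2)
  invisible(x)
}

#' Ingression duration from an annotated trace
#'
#' Onset is the first frame (at or after anaphase onset) whose width is at
#' most `onset_threshold_fraction` times the median pre-anaphase width,
#' sustained for `persistence_frames` consecutive frames; completion is the
#' first frame whose width is at most `completion_width_um`. The duration is
#' `(completion - onset) * frame_interval_min`.
#'
#' @param trace an `ingression_trace`.
#' @return A list with `duration_min`, `onset_frame`, `completion_frame` and
#'   `complete` (logical). When the rule finds no onset or completion inside
#'   the movie, `complete` is `FALSE` and `duration_min` is `NA` rather than
#'   a number.
#' @export
ingression_duration <- function(trace) {
  if (!inherits(trace, "ingression_trace"))
    stop_param("'trace' must be an ingression_trace")
  list(duration_min = trace$duration_min,
       onset_frame = trace$furrow_onset_frame,
       completion_frame = trace$completion_frame,
       complete = !is.na(trace$duration_min))
}

#' Equatorial accumulation onset from time-ordered linescans
#'
#' Detects when the tagged protein becomes enriched at the equatorial
#' cortex: the first profile (relative to anaphase onset) whose mean
#' intensity within `central_halfwidth_um` of the midplane exceeds
#' `enrichment_threshold` times the mean over the outer thirds of the path,
#' sustained for `persistence_frames` profiles.
#'
#' @param profiles list of [linescan_profile()]s, time-ordered, the first
#'   taken at anaphase onset.
#' @param frame_interval_min time between successive profiles (min).
#' @param enrichment_threshold central/outer enrichment ratio that counts as
#'   accumulation.
#' @param persistence_frames consecutive profiles the condition must hold.
#' @param central_halfwidth_um half-width of the equatorial window (um).
#' @return An object of class `accumulation_onset`: `onset_min` (time after
#'   anaphase onset, or `NA` if never), `onset_frame`, and the per-profile
#'   enrichment ratios.
#' @export
accumulation_onset <- function(profiles, frame_interval_min = 1,
                               enrichment_threshold = 1.2,
                               persistence_frames = 2,
                               central_halfwidth_um = 2) {
  if (length(profiles) < persistence_frames)
    stop_param("need at least 'persistence_frames' profiles")
  sp <- vapply(profiles, function(p) p$spacing_um, numeric(1))
  if (max(sp) - min(sp) > 1e-9)
    stop_param("profiles have unequal calibration (spacing)")
  ratio <- vapply(profiles, function(p) {
    central <- abs(p$position_um) <= central_halfwidth_um
    n <- length(p$intensity)
    k <- max(1, floor(n / 3))
    outer_mean <- mean(c(p$intensity[1:k], p$intensity[(n - k + 1):n]))
    if (outer_mean <= 0) return(Inf)
    mean(p$intensity[central]) / outer_mean
  }, numeric(1))
  hit <- ratio > enrichment_threshold
  onset <- NA_integer_
  for (t in seq_len(length(hit) - persistence_frames + 1)) {
    if (all(hit[t:(t + persistence_frames - 1)])) { onset <- t; break }
  }
  structure(list(onset_min = if (is.na(onset)) NA_real_
                             else (onset - 1) * frame_interval_min,
                 onset_frame = onset,
                 enrichment_ratio = ratio,
                 enrichment_threshold = enrichment_threshold,
                 persistence_frames = persistence_frames,
                 central_halfwidth_um = central_halfwidth_um),
            class = "accumulation_onset")
}

#' @export
print.accumulation_onset <- function(x, ...) {
  if (is.na(x$onset_min)) cat("accumulation: not detected\n")
  else cat(sprintf("accumulation onset: %.3g min after anaphase onset\n",
                   x$onset_min))
  invisible(x)
}
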