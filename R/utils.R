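# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All exported generators funnel through this so
# that identical (params, seed) pairs give bit-identical output regardless of
# surrounding RNG use.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: one user-facing seed, documented split
# per stage. Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop_param(sprintf("'%s' must be a finite %s number", name,
                       if (strict) "positive" else "non-negative"))
  x
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != round(x))
    stop_param(sprintf("'%s' must be a positive integer", name))
  as.integer(x)
}

# Bilinear interpolation of a matrix at sub-pixel 0-based (x, y) positions.
# Matrix layout is [y + 1, x + 1] (row = y, col = x), pixel-centre convention.
# Out-of-range coordinates are clamped to the border pixel.
interp_bilinear <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Resolve a region of interest against an image. Accepted forms:
#  * logical matrix of the image's dimensions,
#  * a two-column matrix of 0-based (x, y) pixel coordinates,
#  * a list/vector with named elements x, y, w, h (0-based corner, size).
# Returns the vector of intensities inside the ROI.
roi_values <- function(img, roi, name = "roi") {
  idx <- roi_index(img, roi, name)
  img[idx]
}

roi_index <- function(img, roi, name = "roi") {
  ny <- nrow(img); nx <- ncol(img)
  if (is.logical(roi) && is.matrix(roi)) {
    if (!all(dim(roi) == dim(img)))
      stop_param(sprintf("logical '%s' must match image dimensions", name))
    idx <- which(roi)
  } else if (is.matrix(roi) && ncol(roi) == 2) {
    x <- round(roi[, 1]); y <- round(roi[, 2])
    if (any(x < 0 | x >= nx | y < 0 | y >= ny))
      stop_param(sprintf("'%s' contains out-of-bounds pixels", name))
    idx <- (x) * ny + y + 1
  } else if (!is.null(names(roi)) && all(c("x", "y", "w", "h") %in% names(roi))) {
    r <- as.list(roi)
    xs <- seq(r$x, r$x + r$w - 1); ys <- seq(r$y, r$y + r$h - 1)
    if (any(xs < 0 | xs >= nx) || any(ys < 0 | ys >= ny))
      stop_param(sprintf("'%s' rectangle out of bounds", name))
    idx <- as.vector(outer(ys + 1, xs * ny, `+`))
  } else {
    stop_param(sprintf("unrecognised '%s' specification", name))
  }
  if (length(idx) == 0) stop_param(sprintf("'%s' is empty", name))
  idx
}

#' Rectangular region of interest
#'
#' Convenience constructor for the ROI format accepted throughout the
#' package: a 0-based corner plus width and height, in pixels.
#'
#' @param x,y 0-based pixel coordinates of the top-left corner.
#' @param w,h width and height in pixels.
#' @return A named numeric vector with elements `x`, `y`, `w`, `h`.
#' @export
roi_rect <- function(x, y, w, h) c(x = x, y = y, w = w, h = h)

# Fixed-precision number formatting for CSV/JSON outputs so that reruns with
# the same seed are byte-stable.
fmt_num <- function(x, digits = 8) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "g"))
}
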