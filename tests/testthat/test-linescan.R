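# Cortex path extraction, linescan sampling, normalization and breadth.

test_that("cortex path length on a disk matches the half circumference", {
  mask <- disk_mask(51, 20)
  path <- extract_cortex_path(mask, c(5, 25), c(45, 25), pixel_size_um = 1)
  expect_lt(abs(path$cortex_length_um - pi * 20) / (pi * 20), 0.02)
  # endpoints snap to the poles
  expect_lt(sqrt(sum((path$vertices[1, ] - c(5, 25))^2)), 1)
  n <- nrow(path$vertices)
  expect_lt(sqrt(sum((path$vertices[n, ] - c(45, 25))^2)), 1)
  # midplane crossing sits at position 0 within one sampling step
  i0 <- which.min(abs(path$arc_pos_um))
  expect_lt(abs(path$arc_pos_um[i0]), path$spacing_um)
})

test_that("path extraction validates its inputs", {
  expect_error(extract_cortex_path(matrix(FALSE, 5, 5), c(0, 0), c(4, 4)),
               "empty")
  two <- matrix(FALSE, 11, 11)
  two[2:3, 2:3] <- TRUE; two[8:9, 8:9] <- TRUE
  expect_error(extract_cortex_path(two, c(2, 2), c(8, 8)),
               "exactly one component")
  mask <- disk_mask(51, 20)
  expect_error(extract_cortex_path(mask, c(0, 0), c(45, 25)), "pole1")
})

test_that("linescan of a uniform image is constant at that value", {
  mask <- disk_mask(51, 20)
  path <- extract_cortex_path(mask, c(5, 25), c(45, 25), pixel_size_um = 1)
  img <- matrix(7.5, 51, 51)
  prof <- sample_linescan(img, path)
  expect_true(all(abs(prof$intensity - 7.5) < 1e-9))
})

test_that("wide-line sampling averages perpendicular offsets (stripe oracle)", {
  # vertical stripes; straight horizontal path of width 5 -> the 5
  # perpendicular samples are all in one column, so the profile equals the
  # column values
  img <- matrix(rep(c(0, 100), each = 21, times = 15)[1:(21 * 21)], 21, 21)
  v <- cbind(x = 2:18, y = rep(10, 17))
  path <- manual_cortex_path(v, midplane = rbind(c(10, 0), c(10, 20)),
                             pixel_size_um = 1)
  prof <- sample_linescan(img, path)
  cols <- round(path$vertices[, 1]) + 1
  expect_equal(unname(prof$intensity), unname(img[10, cols]),
               tolerance = 1e-9)
})

test_that("normalization scales the peak to one and is idempotent", {
  pr <- linescan_profile(1:5, c(10, 50, 200, 50, 10), 1, 5)
  n1 <- normalize_profile(pr)
  expect_equal(max(n1$intensity), 1)
  expect_equal(n1$intensity[2], 0.25)
  expect_equal(normalize_profile(n1)$intensity, n1$intensity)
  # scale invariance
  pr2 <- linescan_profile(1:5, 3.7 * c(10, 50, 200, 50, 10), 1, 5)
  expect_equal(normalize_profile(pr2)$intensity, n1$intensity)
  # all-zero profile is an error
  expect_error(normalize_profile(linescan_profile(1:3, c(0, 0, 0), 1, 3)),
               "all-zero")
})

test_that("breadth of a rectangular pulse counts the run times the spacing", {
  y <- c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0)
  pr <- linescan_profile(seq(-2.75, 2.75, by = 0.5), y, 0.5, 6,
                         normalized = TRUE)
  b <- measure_breadth(pr)
  expect_equal(b$breadth_um, 4.0)
  expect_equal(b$n_pixels_counted, 8L)
  expect_equal(b$n_pixels_excluded_outside_peak, 0L)
})

test_that("breadth equals the Gaussian FWHM for zero-baseline bands", {
  pr <- normalize_profile(gaussian_band_profile(1.70, spacing_um = 0.05))
  b <- measure_breadth(pr)
  expect_lt(abs(b$breadth_um - 2 * sqrt(2 * log(2)) * 1.70), 0.05)
})

test_that("above-cutoff samples outside the peak are excluded, not counted", {
  pos <- seq(-5.75, 5.75, by = 0.5)
  y <- rep(0.1, length(pos))
  y[10:15] <- 1                # main run of 6 samples
  y[2] <- 0.6                  # isolated above-cutoff sample far from peak
  pr <- linescan_profile(pos, y, 0.5, 11.5, normalized = TRUE)
  b <- measure_breadth(pr)
  expect_equal(b$breadth_um, 3.0)
  expect_equal(b$n_pixels_excluded_outside_peak, 1L)
  # removing the outlier leaves breadth unchanged
  y2 <- y; y2[2] <- 0.1
  b2 <- measure_breadth(linescan_profile(pos, y2, 0.5, 11.5, normalized = TRUE))
  expect_equal(b2$breadth_um, b$breadth_um)
})

test_that("breadth requires a normalized profile", {
  pr <- linescan_profile(1:4, c(1, 5, 5, 1), 1, 4)
  expect_error(measure_breadth(pr), "normalized")
})

test_that("profile baseline subtraction restores the FWHM oracle", {
  pr <- gaussian_band_profile(1.5, amplitude = 2, baseline = 1,
                              spacing_um = 0.05)
  direct <- measure_breadth(normalize_profile(pr))
  # with the baseline in place the half-maximum sits too low and the
  # breadth is inflated
  expect_gt(direct$breadth_um, 2 * sqrt(2 * log(2)) * 1.5 + 0.5)
  fixed <- measure_breadth(normalize_profile(subtract_profile_baseline(pr)))
  expect_lt(abs(fixed$breadth_um - 2 * sqrt(2 * log(2)) * 1.5), 0.1)
})
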