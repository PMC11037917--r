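# Colony screening: crop, detect, call, plate driver.

make_well <- function(objects = list(), noise_sd = 0, seed = 1,
                      radius = 100) {
  # objects: list of c(x, y, sigma, amplitude)
  sz <- 2 * ceiling(radius * 1.1) + 1
  c0 <- (sz - 1) / 2
  x <- matrix(rep(0:(sz - 1), each = sz), sz, sz)
  y <- matrix(rep(0:(sz - 1), times = sz), sz, sz)
  img <- matrix(100, sz, sz)
  r <- sqrt((x - c0)^2 + (y - c0)^2)
  img[r >= 0.95 * radius] <- 50
  for (o in objects)
    img <- img + o[4] * exp(-((x - c0 - o[1])^2 + (y - c0 - o[2])^2) /
                              (2 * o[3]^2))
  if (noise_sd > 0) img <- img + with_seed(seed, rnorm(sz^2, 0, noise_sd))
  structure(list(well_id = "T1", image = img, well_center_px = c(c0, c0),
                 well_radius_px = radius), class = "well_image")
}

test_that("crop removes the bright well edge from the statistics", {
  w <- make_well()
  w$image[abs(sqrt((row(w$image) - 1 - 110)^2 +
                     (col(w$image) - 1 - 110)^2) - 100) < 2] <- 1e4
  cr <- crop_well(w, margin_fraction = 0.9)
  expect_false(any(w$image[cr$mask] == 1e4))
  det <- detect_colonies(cr)
  expect_equal(det$colony_count, 0)
  full <- crop_well(w, margin_fraction = 1.0)
  expect_gt(sum(full$mask), sum(cr$mask))
})

test_that("one large blob is one colony; sub-minimum specks are debris", {
  w <- make_well(list(c(0, 0, 9, 20)))
  det <- detect_colonies(crop_well(w))
  expect_equal(det$colony_count, 1)
  expect_equal(det$debris_count, 0)
  w2 <- make_well(list(c(0, 0, 9, 20), c(-40, 30, 2.5, 25),
                       c(35, -35, 2.5, 25)))
  det2 <- detect_colonies(crop_well(w2))
  expect_equal(det2$colony_count, 1)
  expect_equal(det2$debris_count, 2)
  expect_length(det2$outlines, 3)
})

test_that("well calls follow the positive/negative/excluded rule", {
  one <- list(colony_count = 1, debris_count = 0, outlines = list())
  expect_equal(call_well(one)$call, "positive")
  none <- list(colony_count = 0, debris_count = 0, outlines = list())
  expect_equal(call_well(none)$call, "negative")
  two <- list(colony_count = 2, debris_count = 0, outlines = list())
  expect_equal(call_well(two)$call, "excluded")
  deb <- list(colony_count = 1, debris_count = 1, outlines = list())
  expect_equal(call_well(deb)$call, "excluded")
  expect_equal(call_well(deb, debris_tolerance = 1)$call, "positive")
})

test_that("raising the threshold never increases the colony count", {
  w <- make_well(list(c(0, 0, 9, 20), c(-40, 30, 8, 12)), noise_sd = 3,
                 seed = 3)
  cr <- crop_well(w)
  counts <- sapply(c(1, 2, 3, 4, 6), function(k)
    detect_colonies(cr, threshold_k = k)$colony_count)
  expect_true(all(diff(counts) <= 0))
})

test_that("screen_plate matches generator truth on a noise-free plate", {
  sim <- simulate_plate_montage(plate_sim_params(noise_sd = 0), seed = 3)
  scr <- screen_plate(sim$wells)
  expect_equal(scr$records$call, sim$truth$call)
  expect_equal(scr$summary$recovery_fraction,
               mean(sim$truth$call == "positive"))
})

test_that("an all-empty plate reports zero recovery", {
  sim <- simulate_plate_montage(plate_sim_params(
    n_wells = 6, colony_count_distribution = c("0" = 1),
    debris_probability = 0), seed = 1)
  scr <- screen_plate(sim$wells)
  expect_equal(scr$summary$recovery_fraction, 0)
})

test_that("duplicate well ids are rejected", {
  sim <- simulate_plate_montage(plate_sim_params(n_wells = 2), seed = 1)
  sim$wells[[2]]$well_id <- sim$wells[[1]]$well_id
  expect_error(screen_plate(sim$wells), "duplicate")
})
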