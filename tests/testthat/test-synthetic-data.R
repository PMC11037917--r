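# Generators: determinism, noise law, geometry and truth bookkeeping.

test_that("identical seeds and parameters give bit-identical movies", {
  p <- small_movie_params(n_frames = 4, img_size_px = 81, cell_radius_um = 3.5)
  a <- simulate_division_movie(p, seed = 7)
  b <- simulate_division_movie(p, seed = 7)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$furrow_width_um, b$truth$furrow_width_um)
  c <- simulate_division_movie(p, seed = 8)
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("noise-free limit: constant frame means, vanishing relative noise", {
  p <- small_movie_params(n_frames = 3, n_z = 1, img_size_px = 81,
                          cell_radius_um = 3.5, bleach_rate = 0,
                          read_noise_sd = 0, exposure_gain = 1000)
  sim <- simulate_division_movie(p, seed = 1)
  # pre-furrow frames have identical geometry; means agree to ~1/sqrt(gain)
  m <- sapply(1:3, function(t) mean(sim$stack$voxels[t, 1, 1, , ]))
  expect_lt(max(abs(m - m[1])) / m[1], 1e-3)
})

test_that("Poisson stage has variance equal to mean within 5 percent", {
  lam <- array(50, dim = c(1, 1, 1, 120, 120))   # 14400 pixels
  v <- with_seed(3, knockintools:::apply_camera(lam, exposure_gain = 1,
                                                read_noise_sd = 0))
  expect_lt(abs(stats::var(as.vector(v)) / mean(v) - 1), 0.05)
  # additive read noise adds its variance
  v2 <- with_seed(3, knockintools:::apply_camera(lam, 1, read_noise_sd = 4))
  expect_lt(abs(stats::var(as.vector(v2)) - (50 + 16)) / 66, 0.08)
})

test_that("truth furrow width follows the piecewise-linear law exactly", {
  p <- small_movie_params(n_frames = 30, img_size_px = 61,
                          cell_radius_um = 2.5, furrow_onset_min = 5,
                          ingression_rate_um_per_min = 0.4)
  sim <- simulate_division_movie(p, seed = 1)
  t_min <- 0:29
  expected <- pmax(5 - 0.4 * pmax(t_min - 5, 0), 0)
  expect_equal(sim$truth$furrow_width_um, expected)
  # non-increasing after onset
  expect_true(all(diff(sim$truth$furrow_width_um[6:30]) <= 0))
})

test_that("exposure pairs share geometry and differ only in noise scale", {
  p <- small_movie_params(n_frames = 1, n_z = 1, img_size_px = 101,
                          cell_radius_um = 4)
  pair <- simulate_exposure_pair(p, low = list(exposure_gain = 1, read_noise_sd = 0),
                                 high = list(exposure_gain = 9, read_noise_sd = 0),
                                 seed = 4)
  expect_identical(dim(pair$low$voxels), dim(pair$high$voxels))
  # identical settings -> exchangeable outputs (equal means within MC error)
  same <- simulate_exposure_pair(p, low = list(exposure_gain = 2, read_noise_sd = 1),
                                 high = list(exposure_gain = 2, read_noise_sd = 1),
                                 seed = 4)
  m1 <- mean(same$low$voxels); m2 <- mean(same$high$voxels)
  expect_lt(abs(m1 - m2) / m1, 0.01)
})

test_that("shot-noise scaling: SNR ratio approaches sqrt(gain ratio)", {
  p <- small_movie_params(n_frames = 1, n_z = 1, img_size_px = 101,
                          cell_radius_um = 4)
  sig <- roi_rect(44, 44, 12, 12)
  bg <- roi_rect(2, 2, 10, 10)
  ratios <- sapply(1:12, function(s) {
    pair <- simulate_exposure_pair(p, low = list(exposure_gain = 1, read_noise_sd = 0),
                                   high = list(exposure_gain = 9, read_noise_sd = 0),
                                   seed = s)
    lo <- measure_snr(matrix(pair$low$voxels[1, 1, 1, , ], 101, 101), sig, bg)
    hi <- measure_snr(matrix(pair$high$voxels[1, 1, 1, , ], 101, 101), sig, bg)
    hi$snr / lo$snr
  })
  expect_lt(abs(mean(ratios) - 3) / 3, 0.10)
})

test_that("plate truth records the realized colony and debris draws", {
  p <- plate_sim_params(n_wells = 96)
  sim <- simulate_plate_montage(p, seed = 6)
  expect_equal(nrow(sim$truth), 96)
  expect_setequal(unique(sim$truth$n_colonies), c(0, 1, 2))
  # truth call rule
  with(sim$truth, {
    expect_true(all(call[n_colonies == 1 & n_debris == 0] == "positive"))
    expect_true(all(call[n_colonies > 1 | n_debris > 0] == "excluded"))
    expect_true(all(call[n_colonies == 0 & n_debris == 0] == "negative"))
  })
  # degenerate distributions
  s0 <- simulate_plate_montage(plate_sim_params(
    n_wells = 8, colony_count_distribution = c("0" = 1),
    debris_probability = 0), seed = 1)
  expect_true(all(s0$truth$call == "negative"))
  s1 <- simulate_plate_montage(plate_sim_params(
    n_wells = 8, colony_count_distribution = c("1" = 1),
    debris_probability = 0), seed = 1)
  expect_true(all(s1$truth$call == "positive"))
})

test_that("realized colony counts follow the requested multinomial", {
  probs <- c("0" = 0.5, "1" = 0.3, "2" = 0.2)
  counts <- integer(3)
  for (s in 1:12) {
    sim <- simulate_plate_montage(plate_sim_params(
      n_wells = 96, colony_count_distribution = probs), seed = s)
    counts <- counts + tabulate(sim$truth$n_colonies + 1, 3)
  }
  gof <- stats::chisq.test(counts, p = probs)
  expect_gt(gof$p.value, 0.001)
})

test_that("zero-error reads match their source alleles with barcodes intact", {
  tg <- test_target()
  p <- read_sim_params(targets = list(tg), per_base_error_rate = 0,
                       n_reads = 60,
                       allele_mixture = c(WT = 0.5, INDEL = 0, HDR = 0.5,
                                          HDR_MUTANT = 0))
  sim <- simulate_amplicon_reads(p, seed = 2)
  fwd <- sim$truth$orientation == "forward"
  seqs <- sim$reads$sequence
  seqs[!fwd] <- knockintools:::revcomp(seqs[!fwd])
  wt_read <- paste0(tg$gene_barcodes[1], tg$wt_reference,
                    knockintools:::revcomp(tg$gene_barcodes[2]))
  hdr_read <- paste0(tg$gene_barcodes[1], tg$hdr_reference,
                     knockintools:::revcomp(tg$gene_barcodes[2]))
  expect_true(all(seqs[sim$truth$class == "WT"] == wt_read))
  expect_true(all(seqs[sim$truth$class == "HDR"] == hdr_read))
})

test_that("all-HDR mixture labels every read HDR", {
  p <- read_sim_params(n_reads = 30,
                       allele_mixture = c(WT = 0, INDEL = 0, HDR = 1,
                                          HDR_MUTANT = 0))
  sim <- simulate_amplicon_reads(p, seed = 3)
  expect_true(all(sim$truth$class == "HDR"))
})

test_that("realized mixture fractions stay within binomial sampling error", {
  p <- read_sim_params(n_reads = 10000, per_base_error_rate = 0)
  sim <- simulate_amplicon_reads(p, seed = 4)
  phat <- mean(sim$truth$class == "HDR")
  expect_lt(abs(phat - 0.375), 3 * sqrt(0.375 * 0.625 / 10000))
})

test_that("parameter validation rejects invalid settings", {
  expect_error(cell_sim_params(cell_radius_um = -1), "positive")
  expect_error(cell_sim_params(bleach_rate = 1), "bleach_rate")
  expect_error(plate_sim_params(colony_count_distribution = c("0" = 0.5)),
               "probability")
  expect_error(read_sim_params(allele_mixture = c(WT = 0.5, INDEL = 0.2,
                                                  HDR = 0.2, HDR_MUTANT = 0)),
               "sum to 1")
  expect_error(target_spec("g", "", 0, gene_barcodes = c("AA", "CC")),
               "empty")
})
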