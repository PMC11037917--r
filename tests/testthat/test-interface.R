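# Batch drivers: IO round-trips, pipeline/unit equivalence, conservation
# and reproducibility.

small_sim_config <- function(dir, seed = 5) {
  list(out_dir = dir, seed = seed,
       movie = list(n_frames = 5, n_z = 2, img_size_px = 81,
                    cell_radius_um = 3.5),
       plate = list(n_wells = 6),
       reads = list(n_reads = 120))
}

test_that("stack TIFF round-trips exactly through the sidecar metadata", {
  p <- small_movie_params(n_frames = 2, n_z = 2, img_size_px = 41,
                          cell_radius_um = 1.5)
  sim <- simulate_division_movie(p, seed = 1)
  f <- file.path(withr::local_tempdir(), "m.tif")
  write_stack_tiff(sim$stack, f)
  back <- read_stack_tiff(f)
  expect_equal(back$voxels, sim$stack$voxels, tolerance = 1e-6)
  expect_equal(back$pixel_size_um, p$pixel_size_um)
  expect_equal(back$channel_roles, c(tag = 1L, chromatin = 2L))
})

test_that("FASTQ round-trips sequences and qualities", {
  p <- read_sim_params(n_reads = 25)
  sim <- simulate_amplicon_reads(p, seed = 2)
  f <- file.path(withr::local_tempdir(), "r.fastq")
  write_fastq(sim$reads, f)
  back <- read_fastq(f)
  expect_equal(back$sequence, sim$reads$sequence)
  expect_equal(back$quality, sim$reads$quality)
  expect_equal(back$mean_q, sim$reads$mean_q, tolerance = 1e-9)
})

test_that("target tables round-trip through FASTA + CSV", {
  tg <- test_target()
  d <- withr::local_tempdir()
  write_targets(list(tg), file.path(d, "ref.fasta"), file.path(d, "t.csv"))
  back <- read_targets(file.path(d, "ref.fasta"), file.path(d, "t.csv"))[[1]]
  expect_equal(back$wt_reference, tg$wt_reference)
  expect_equal(back$hdr_reference, tg$hdr_reference)
  expect_equal(back$gene_barcodes, unname(tg$gene_barcodes))
  expect_equal(back$cut_position, tg$cut_position)
})

test_that("configs load from YAML and JSON files", {
  d <- withr::local_tempdir()
  yml <- file.path(d, "c.yaml")
  writeLines(c("seed: 4", "what: [reads]", "reads:", "  n_reads: 10"), yml)
  cfg <- load_config(yml)
  expect_equal(cfg$seed, 4)
  expect_equal(cfg$reads$n_reads, 10)
  jsn <- file.path(d, "c.json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  expect_equal(load_config(jsn)$reads$n_reads, 10)
  expect_error(load_config(file.path(d, "missing.yaml")), "not found")
})

test_that("simulate driver writes loadable data and is seed-stable", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulate(small_sim_config(d1))
  run_simulate(small_sim_config(d2))
  for (f in c("movie_truth.json", "plate_truth.csv", "reads_truth.csv",
              "reads.fastq", "plate_layout.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  expect_identical(readBin(file.path(d1, "movie.tif"), "raw", 1e8),
                   readBin(file.path(d2, "movie.tif"), "raw", 1e8))
  st <- read_stack_tiff(file.path(d1, "movie.tif"))
  expect_equal(dim(st$voxels)[1], 5)
})

test_that("quantify driver reproduces direct calls of the pipeline", {
  d <- withr::local_tempdir()
  p <- cell_sim_params(n_z = 3)
  sim <- simulate_division_movie(p, seed = 3)
  mv <- file.path(d, "movie.tif")
  write_stack_tiff(sim$stack, mv)
  out <- run_quantify(list(movie = mv, out_dir = file.path(d, "q"),
                           anaphase_onset_frame =
                             sim$truth$anaphase_onset_frame))
  res <- utils::read.csv(out[["trace"]])
  direct <- quantify_movie(read_stack_tiff(mv),
                           sim$truth$anaphase_onset_frame)
  expect_equal(res$furrow_width_um, direct$trace$furrow_width_um,
               tolerance = 1e-6)
  smry <- jsonlite::read_json(file.path(d, "q", "quantify_summary.json"))
  expect_equal(smry$duration_min, direct$trace$duration_min)
  bre <- utils::read.csv(file.path(d, "q", "breadth.csv"))
  expect_equal(bre$breadth_um, direct$breadth$breadth_um, tolerance = 1e-6)
})

test_that("screen driver matches truth on noise-free simulated plates", {
  d <- withr::local_tempdir()
  cfg <- list(out_dir = d, seed = 2, what = "plate",
              plate = list(n_wells = 12, noise_sd = 0))
  run_simulate(cfg)
  out <- run_screen_plate(list(plate_dir = file.path(d, "plate"),
                               layout = file.path(d, "plate_layout.csv"),
                               out_dir = file.path(d, "scr")))
  rec <- utils::read.csv(out[["records"]])
  truth <- utils::read.csv(file.path(d, "plate_truth.csv"))
  expect_equal(rec$call, truth$call)
  smry <- jsonlite::read_json(out[["summary"]])
  expect_equal(smry$recovery_fraction, mean(truth$call == "positive"))
})

test_that("genotype driver conserves reads across output categories", {
  d <- withr::local_tempdir()
  cfg <- list(out_dir = d, seed = 6, what = "reads",
              reads = list(n_reads = 300))
  run_simulate(cfg)
  out <- run_genotype(list(fastq = file.path(d, "reads.fastq"),
                           references = file.path(d, "references.fasta"),
                           targets = file.path(d, "targets.csv"),
                           out_dir = file.path(d, "g"),
                           max_mismatch = 1, with_indels = TRUE))
  smry <- jsonlite::read_json(file.path(d, "g", "genotype_summary.json"))
  expect_equal(smry$n_assigned + smry$n_unassigned + smry$n_low_q,
               smry$n_input)
  calls <- utils::read.csv(out[["calls"]])
  expect_equal(nrow(calls), smry$n_assigned)
  # zero-error run recovers the truth mixture exactly
  d2 <- withr::local_tempdir()
  run_simulate(list(out_dir = d2, seed = 6, what = "reads",
                    reads = list(n_reads = 200, per_base_error_rate = 0)))
  out2 <- run_genotype(list(fastq = file.path(d2, "reads.fastq"),
                            references = file.path(d2, "references.fasta"),
                            targets = file.path(d2, "targets.csv"),
                            out_dir = file.path(d2, "g")))
  fr <- utils::read.csv(out2[["frequencies"]])
  truth <- utils::read.csv(file.path(d2, "reads_truth.csv"))
  truth$class[truth$class == "HDR_MUTANT"] <- "HDR"
  expect_equal(fr$hdr, mean(truth$class == "HDR"), tolerance = 1e-9)
  expect_equal(fr$wt, mean(truth$class == "WT"), tolerance = 1e-9)
})

test_that("stats driver writes summaries and the right test family", {
  d <- withr::local_tempdir()
  df <- data.frame(value = c(rnorm(8), rnorm(8, 1), rnorm(8, 0, 2)),
                   group = rep(c("a", "b", "c"), each = 8))
  inp <- file.path(d, "in.csv")
  utils::write.csv(df, inp, row.names = FALSE)
  out <- run_stats(list(input = inp, out_dir = file.path(d, "s")))
  expect_true(file.exists(out[["tests"]]))
  tests <- utils::read.csv(out[["tests"]])
  expect_setequal(tests$test, c("welch_anova", "brown_forsythe_anova"))
  pw <- utils::read.csv(out[["pairwise"]])
  expect_equal(nrow(pw), 3)
})
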