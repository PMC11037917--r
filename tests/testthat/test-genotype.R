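# Read filtering, demultiplexing, allele classification and genotype calls.

test_that("mean-Q filter excludes strictly below the cutoff", {
  q10 <- knockintools:::phred_string(rep(10, 50))
  q9 <- knockintools:::phred_string(rep(9, 50))
  reads <- data.frame(id = c("a", "b"),
                      sequence = strrep("ACGT", 25)[c(1, 1)],
                      quality = c(q10, q9), stringsAsFactors = FALSE)
  kept <- filter_reads(reads, min_q = 10)
  expect_equal(kept$id, "a")
  expect_equal(nrow(filter_reads(reads[0, ], 10)), 0)
  bad <- reads; bad$quality <- NULL
  expect_error(filter_reads(bad), "quality")
})

test_that("read-level Q is the Phred of the mean error probability", {
  # bases at Q10 and Q20 -> mean p = (0.1 + 0.01)/2 -> Q ~ 12.6
  q <- knockintools:::phred_string(c(10, 20))
  expect_equal(read_mean_q(q), -10 * log10(0.055), tolerance = 1e-6)
})

test_that("demultiplexing assigns by barcode presence in both orientations", {
  tg <- test_target()
  p <- read_sim_params(targets = list(tg), per_base_error_rate = 0,
                       n_reads = 80)
  sim <- simulate_amplicon_reads(p, seed = 8)
  dmx <- demultiplex(sim$reads, list(tg), mode = "population")
  expect_true(all(dmx$assignments$assigned))
  expect_equal(unname(lengths(dmx$bins)[tg$gene]), 80L)
  # both orientations occur in the input
  expect_setequal(unique(sim$truth$orientation), c("forward", "reverse"))
  # a read with no barcode is unassigned
  alien <- data.frame(id = "x", sequence = strrep("ACGT", 60),
                      stringsAsFactors = FALSE)
  d2 <- demultiplex(alien, list(tg), mode = "population")
  expect_equal(d2$unassigned, 1L)
})

test_that("clone mode requires both gene and clone barcodes", {
  tg <- test_target()
  cbcs <- with_seed(42, make_barcodes(2))
  names(cbcs) <- c("cl1", "cl2")
  p <- read_sim_params(targets = list(tg), per_base_error_rate = 0,
                       n_reads = 40, clone_barcodes = cbcs)
  sim <- simulate_amplicon_reads(p, seed = 8)
  dmx <- demultiplex(sim$reads, list(tg), mode = "clone",
                     clone_barcodes = cbcs)
  expect_true(all(dmx$assignments$assigned))
  expect_equal(dmx$assignments$clone, sim$truth$clone)
  # gene barcode present but no clone barcode -> unassigned
  pop <- simulate_amplicon_reads(read_sim_params(targets = list(tg),
                                                 per_base_error_rate = 0,
                                                 n_reads = 10), seed = 1)
  d2 <- demultiplex(pop$reads, list(tg), mode = "clone",
                    clone_barcodes = cbcs)
  expect_equal(length(d2$unassigned), 10L)
})

test_that("classification handles the canonical read types exactly", {
  tg <- test_target()
  rc <- knockintools:::revcomp
  wt_read <- paste0(tg$gene_barcodes[1], tg$wt_reference,
                    rc(tg$gene_barcodes[2]))
  hdr_read <- paste0(tg$gene_barcodes[1], tg$hdr_reference,
                     rc(tg$gene_barcodes[2]))
  cut <- tg$cut_position
  del4 <- paste0(tg$gene_barcodes[1],
                 paste0(substr(tg$wt_reference, 1, cut),
                        substr(tg$wt_reference, cut + 5,
                               nchar(tg$wt_reference))),
                 rc(tg$gene_barcodes[2]))
  # hdr with 3 substitutions inside the tag
  tag_start <- tg$insert_start + nchar(tg$linker_sequence) + 1
  ch <- strsplit(tg$hdr_reference, "")[[1]]
  for (pos in tag_start + c(5, 15, 25))
    ch[pos] <- chartr("ACGT", "GTAC", ch[pos])
  mut_read <- paste0(tg$gene_barcodes[1], paste(ch, collapse = ""),
                     rc(tg$gene_barcodes[2]))
  reads <- data.frame(id = c("wt", "hdr", "del", "mut"),
                      sequence = c(wt_read, hdr_read, del4, mut_read),
                      stringsAsFactors = FALSE)
  clone <- classify_reads(reads, tg, mode = "clone")
  expect_equal(clone$class, c("WT", "HDR", "INDEL", "HDR_MUTANT"))
  expect_equal(clone$tag_mismatches[4], 3L)
  expect_equal(clone$indel_size[3], 4L)
  pop <- classify_reads(reads, tg, mode = "population")
  expect_equal(pop$class, c("WT", "HDR", "INDEL", "HDR"))
  # reverse-complemented reads classify identically
  rc_reads <- reads; rc_reads$sequence <- rc(reads$sequence)
  expect_equal(classify_reads(rc_reads, tg, mode = "clone")$class,
               clone$class)
})

test_that("short or unalignable reads are ambiguous, not errors", {
  tg <- test_target()
  reads <- data.frame(id = c("short", "junk"),
                      sequence = c("ACGTACGTAC",
                                   strrep("ATATATATAT", 25)),
                      stringsAsFactors = FALSE)
  cl <- classify_reads(reads, tg)
  expect_equal(cl$class, c("AMBIGUOUS", "AMBIGUOUS"))
})

test_that("zero-error classification equals generator truth for all classes", {
  tg <- test_target()
  p <- read_sim_params(targets = list(tg), per_base_error_rate = 0,
                       n_reads = 200,
                       allele_mixture = c(WT = 0.25, INDEL = 0.25,
                                          HDR = 0.25, HDR_MUTANT = 0.25))
  sim <- simulate_amplicon_reads(p, seed = 11)
  cl <- classify_reads(sim$reads, tg, mode = "clone")
  expect_equal(cl$class, sim$truth$class)
})

test_that("population fractions are computed over classified reads", {
  calls <- c(rep("WT", 5), rep("INDEL", 3), rep("HDR", 2))
  pf <- population_frequencies(calls)
  expect_equal(unname(pf$fractions), c(0.50, 0.30, 0.20))
  expect_equal(sum(pf$fractions), 1)
  all_hdr <- population_frequencies(rep("HDR", 10))
  expect_equal(unname(all_hdr$fractions["HDR"]), 1)
  # HDR_MUTANT merges into HDR; ambiguous counted separately
  pf2 <- population_frequencies(c("HDR", "HDR_MUTANT", "AMBIGUOUS"))
  expect_equal(unname(pf2$fractions["HDR"]), 1)
  expect_equal(pf2$n_ambiguous, 1L)
  expect_error(population_frequencies(rep("AMBIGUOUS", 3)), "no classified")
})

test_that("clone genotype calls follow the candidate-allele rule", {
  het <- call_clone_genotype(c(rep("HDR", 52), rep("INDEL", 48)))
  expect_equal(het$zygosity, "heterozygous")
  expect_setequal(het$alleles, c("HDR", "INDEL"))
  hom <- call_clone_genotype(c(rep("HDR", 97), rep("WT", 3)))
  expect_equal(hom$zygosity, "homozygous")
  expect_equal(hom$alleles, c("HDR", "HDR"))
  amb <- call_clone_genotype(c(rep("HDR", 40), rep("INDEL", 30),
                               rep("WT", 30)))
  expect_equal(amb$zygosity, "ambiguous")
  expect_warning(low <- call_clone_genotype(rep("HDR", 10)), "ambiguous")
  expect_equal(low$zygosity, "ambiguous")
})

test_that("population HDR equals clone HDR plus HDR_MUTANT on the same reads", {
  tg <- test_target()
  p <- read_sim_params(targets = list(tg), n_reads = 400,
                       allele_mixture = c(WT = 0.3, INDEL = 0.2, HDR = 0.3,
                                          HDR_MUTANT = 0.2))
  sim <- simulate_amplicon_reads(p, seed = 9)
  pop <- classify_reads(sim$reads, tg, mode = "population")
  clo <- classify_reads(sim$reads, tg, mode = "clone")
  expect_identical(sum(pop$class == "HDR"),
                   sum(clo$class %in% c("HDR", "HDR_MUTANT")))
})
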