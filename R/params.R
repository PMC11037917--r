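#' Parameters for the dividing-cell movie simulator
#'
#' Builds and validates the parameter set used by
#' [simulate_division_movie()]. The defaults describe a mitotic stem cell
#' with a cortically enriched tagged protein: a ~14 um diameter cell imaged
#' at 0.2 um/pixel with 9 z-slices every minute, an equatorial band whose
#' Gaussian profile has `band_sigma_um` SD (full width at half maximum
#' 2*sqrt(2*log(2))*sigma, approximately 4.1 um at the default sigma), a
#' furrow that starts ingressing at `furrow_onset_min` and closes linearly at
#' `ingression_rate_um_per_min`, exponential photobleaching, and a
#' Poisson-Gaussian camera model.
#'
#' @param cell_radius_um cell radius (um).
#' @param band_sigma_um SD of the Gaussian equatorial band, measured as arc
#'   distance along the cortex (um).
#' @param cortical_ratio peak intensity of the equatorial band relative to the
#'   cytosol mean (> 1).
#' @param metaphase_cortical_ratio uniform cortical enrichment applied to the
#'   whole cortex shell (1 = none); used to emulate proteins that are
#'   cortically enriched already in metaphase.
#' @param cytosol_level expected photons/pixel in the cytosol.
#' @param background_level expected photons/pixel outside the cell.
#' @param chromatin_level peak photons/pixel of the chromatin channel.
#' @param bleach_rate per-frame fractional intensity decay in `[0, 1)`.
#' @param anaphase_onset_min time of anaphase onset (min).
#' @param accumulation_onset_min time at which the equatorial band appears
#'   (min, absolute movie time).
#' @param furrow_onset_min time at which furrow ingression starts (min).
#' @param ingression_rate_um_per_min linear furrow closure rate (um/min).
#' @param frame_interval_min time between frames (min).
#' @param n_frames,n_z number of timepoints and z-slices.
#' @param pixel_size_um pixel size (um).
#' @param cortex_thickness_um apparent thickness of the rendered cortex
#'   shell (um); reflects the optically blurred cortex, sized so the
#'   5-pixel measurement line samples within the shell.
#' @param exposure_gain photon-collection scale of the exposure setting;
#'   expected photon counts are `exposure_gain` times the scene intensity.
#' @param read_noise_sd SD of the additive Gaussian camera read noise
#'   (counts).
#' @param img_size_px image side length (pixels); defaults to a field
#'   comfortably containing the fully divided cell.
#' @return An object of class `cell_sim_params` (a validated list).
#' @seealso [simulate_division_movie()], [simulate_metaphase_cell()]
#' @export
cell_sim_params <- function(cell_radius_um = 7,
                            band_sigma_um = 1.74,
                            cortical_ratio = 1.5,
                            metaphase_cortical_ratio = 1,
                            cytosol_level = 50,
                            background_level = 10,
                            chromatin_level = 120,
                            bleach_rate = 0.01,
                            anaphase_onset_min = 4,
                            accumulation_onset_min = 8,
                            furrow_onset_min = 9,
                            ingression_rate_um_per_min = 0.65,
                            frame_interval_min = 1,
                            n_frames = 34,
                            n_z = 9,
                            pixel_size_um = 0.2,
                            cortex_thickness_um = 1.4,
                            exposure_gain = 1,
                            read_noise_sd = 2,
                            img_size_px = NULL) {
  check_positive(cell_radius_um, "cell_radius_um")
  check_positive(band_sigma_um, "band_sigma_um")
  if (!is.numeric(cortical_ratio) || cortical_ratio <= 1)
    stop_param("'cortical_ratio' must be > 1")
  if (!is.numeric(metaphase_cortical_ratio) || metaphase_cortical_ratio < 1)
    stop_param("'metaphase_cortical_ratio' must be >= 1")
  check_positive(cytosol_level, "cytosol_level", strict = FALSE)
  check_positive(background_level, "background_level", strict = FALSE)
  check_positive(chromatin_level, "chromatin_level", strict = FALSE)
  if (!is.numeric(bleach_rate) || bleach_rate < 0 || bleach_rate >= 1)
    stop_param("'bleach_rate' must lie in [0, 1)")
  check_positive(anaphase_onset_min, "anaphase_onset_min", strict = FALSE)
  check_positive(accumulation_onset_min, "accumulation_onset_min", strict = FALSE)
  check_positive(furrow_onset_min, "furrow_onset_min", strict = FALSE)
  check_positive(ingression_rate_um_per_min, "ingression_rate_um_per_min")
  check_positive(frame_interval_min, "frame_interval_min")
  n_frames <- check_count(n_frames, "n_frames")
  n_z <- check_count(n_z, "n_z")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(cortex_thickness_um, "cortex_thickness_um")
  check_positive(exposure_gain, "exposure_gain")
  check_positive(read_noise_sd, "read_noise_sd", strict = FALSE)
  if (is.null(img_size_px)) {
    # field wide enough for the two fully separated lobes along x
    img_size_px <- 2 * ceiling(2.2 * cell_radius_um / pixel_size_um) + 1
  }
  img_size_px <- check_count(img_size_px, "img_size_px")
  structure(list(
    cell_radius_um = cell_radius_um, band_sigma_um = band_sigma_um,
    cortical_ratio = cortical_ratio,
    metaphase_cortical_ratio = metaphase_cortical_ratio,
    cytosol_level = cytosol_level, background_level = background_level,
    chromatin_level = chromatin_level, bleach_rate = bleach_rate,
    anaphase_onset_min = anaphase_onset_min,
    accumulation_onset_min = accumulation_onset_min,
    furrow_onset_min = furrow_onset_min,
    ingression_rate_um_per_min = ingression_rate_um_per_min,
    frame_interval_min = frame_interval_min, n_frames = n_frames, n_z = n_z,
    pixel_size_um = pixel_size_um, cortex_thickness_um = cortex_thickness_um,
    exposure_gain = exposure_gain, read_noise_sd = read_noise_sd,
    img_size_px = img_size_px), class = "cell_sim_params")
}

#' Parameters for the 96-well plate montage simulator
#'
#' @param n_wells number of wells (default 96, named A1..H12).
#' @param colony_count_distribution named numeric vector of probabilities over
#'   colony counts `0, 1, 2, ...`; names are the counts. Together with
#'   `debris_probability`, the default places single clean colonies in about
#'   61% of wells, the plate-level clonal recovery the screen reports.
#' @param colony_radius_range_px colony radius range (pixels).
#' @param colony_amplitude peak colony intensity above background.
#' @param debris_probability probability that a well contains one debris
#'   speck.
#' @param debris_size_px debris radius (pixels); must stay below the minimum
#'   colony area used by the detector.
#' @param well_radius_px well radius (pixels).
#' @param edge_darkening multiplicative darkening of the well edge ring.
#' @param background_level mean background intensity.
#' @param background_gradient amplitude of a linear background ramp.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @return An object of class `plate_sim_params`.
#' @seealso [simulate_plate_montage()]
#' @export
plate_sim_params <- function(n_wells = 96,
                             colony_count_distribution = c("0" = 0.30,
                                                           "1" = 0.65,
                                                           "2" = 0.05),
                             colony_radius_range_px = c(16, 20),
                             colony_amplitude = 15,
                             debris_probability = 0.05,
                             debris_size_px = 4,
                             well_radius_px = 100,
                             edge_darkening = 0.5,
                             background_level = 100,
                             background_gradient = 5,
                             noise_sd = 3) {
  n_wells <- check_count(n_wells, "n_wells")
  p <- colony_count_distribution
  if (is.null(names(p)) || any(is.na(suppressWarnings(as.integer(names(p))))))
    stop_param("'colony_count_distribution' must be named by integer counts")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_param("'colony_count_distribution' must be a probability vector")
  if (length(colony_radius_range_px) != 2 || any(colony_radius_range_px <= 0) ||
      diff(colony_radius_range_px) < 0)
    stop_param("'colony_radius_range_px' must be an increasing positive pair")
  check_positive(colony_amplitude, "colony_amplitude")
  if (debris_probability < 0 || debris_probability > 1)
    stop_param("'debris_probability' must lie in [0, 1]")
  check_positive(debris_size_px, "debris_size_px")
  # debris must be smaller than any detectable colony
  if (pi * debris_size_px^2 >= pi * min(colony_radius_range_px)^2 / 2)
    stop_param("'debris_size_px' too large relative to colonies")
  check_positive(well_radius_px, "well_radius_px")
  if (edge_darkening < 0 || edge_darkening > 1)
    stop_param("'edge_darkening' must lie in [0, 1]")
  check_positive(background_level, "background_level", strict = FALSE)
  check_positive(background_gradient, "background_gradient", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  structure(list(
    n_wells = n_wells, colony_count_distribution = p,
    colony_radius_range_px = colony_radius_range_px,
    colony_amplitude = colony_amplitude,
    debris_probability = debris_probability, debris_size_px = debris_size_px,
    well_radius_px = well_radius_px, edge_darkening = edge_darkening,
    background_level = background_level,
    background_gradient = background_gradient, noise_sd = noise_sd),
    class = "plate_sim_params")
}

# Default synthetic 48-nt tag coding sequence (16 codons) preceded by a
# 9-nt triple-glycine linker. The tag sequence is a synthetic stand-in with
# the correct length and structure, not a published sequence.
default_tag_sequence <- function() {
  "ACCGAGCTGAACTTCAAGGAATGGCAAAAGGCCTTTACCGATATGATG"
}

default_linker_sequence <- function() "GGAGGTGGA"

#' Parameters for the amplicon read simulator
#'
#' Describes one or more target loci (wild-type reference plus the
#' knock-in reference carrying a linker+tag insertion at the cut site), an
#' allele mixture, a per-base error model and the dual-barcode layout used
#' for Nanopore-style amplicon pools.
#'
#' @param targets list of target specs built with [target_spec()]. When
#'   `NULL`, one synthetic default target is generated from `seed_refs`.
#' @param allele_mixture named fractions over
#'   `WT`, `INDEL`, `HDR`, `HDR_MUTANT`; must sum to 1.
#' @param indel_size_distribution named probability vector over indel sizes
#'   (positive = insertion, negative = deletion). Sizes of magnitude >= 3 by
#'   default: 1-2 bp edits are not reliably separable from sequencing indel
#'   noise in single long reads at the simulated error rate.
#' @param per_base_error_rate total per-base sequencing error rate in
#'   `[0, 1)`; split 80/10/10 between substitutions, insertions and
#'   deletions.
#' @param mean_q,sd_q per-base quality model (Phred mean and SD).
#' @param tag_mutations number of substitutions placed in the tag of
#'   `HDR_MUTANT` alleles (range sampled per read).
#' @param clone_barcodes optional named character vector of clone barcodes;
#'   when supplied, reads carry a clone barcode pair in addition to the gene
#'   barcodes (clone-mode layout).
#' @param n_reads number of reads to simulate.
#' @param seed_refs seed used to draw the synthetic default reference when
#'   `targets` is `NULL`.
#' @return An object of class `read_sim_params`.
#' @seealso [simulate_amplicon_reads()], [target_spec()]
#' @export
read_sim_params <- function(targets = NULL,
                            allele_mixture = c(WT = 0.10, INDEL = 0.525,
                                               HDR = 0.375, HDR_MUTANT = 0),
                            indel_size_distribution = c("-7" = 0.25, "-5" = 0.2,
                                                        "-3" = 0.2, "3" = 0.15,
                                                        "5" = 0.1, "10" = 0.1),
                            per_base_error_rate = 0.05,
                            mean_q = 14, sd_q = 2.5,
                            tag_mutations = c(3, 8),
                            clone_barcodes = NULL,
                            n_reads = 1000,
                            seed_refs = 20) {
  if (is.null(targets)) targets <- list(synthetic_target(seed = seed_refs))
  if (!is.list(targets) || !all(vapply(targets, inherits, TRUE, "target_spec")))
    stop_param("'targets' must be a list of target_spec objects")
  m <- allele_mixture
  need <- c("WT", "INDEL", "HDR", "HDR_MUTANT")
  if (!all(names(m) %in% need)) stop_param("unknown allele class in mixture")
  m <- m[need]; m[is.na(m)] <- 0; names(m) <- need
  if (any(m < 0) || abs(sum(m) - 1) > 1e-9)
    stop_param("'allele_mixture' must be non-negative and sum to 1")
  sz <- suppressWarnings(as.integer(names(indel_size_distribution)))
  if (any(is.na(sz)) || any(sz == 0))
    stop_param("'indel_size_distribution' must be named by non-zero sizes")
  if (any(indel_size_distribution < 0) ||
      abs(sum(indel_size_distribution) - 1) > 1e-9)
    stop_param("'indel_size_distribution' must be a probability vector")
  if (per_base_error_rate < 0 || per_base_error_rate >= 1)
    stop_param("'per_base_error_rate' must lie in [0, 1)")
  check_positive(mean_q, "mean_q")
  check_positive(sd_q, "sd_q", strict = FALSE)
  n_reads <- check_count(n_reads, "n_reads")
  if (!is.null(clone_barcodes)) {
    if (is.null(names(clone_barcodes)) || anyDuplicated(clone_barcodes))
      stop_param("'clone_barcodes' must be a named vector of unique sequences")
  }
  all_bc <- c(unlist(lapply(targets, `[[`, "gene_barcodes")), clone_barcodes)
  check_barcode_set(all_bc)
  structure(list(
    targets = targets, allele_mixture = m,
    indel_size_distribution = indel_size_distribution,
    per_base_error_rate = per_base_error_rate,
    mean_q = mean_q, sd_q = sd_q, tag_mutations = tag_mutations,
    clone_barcodes = clone_barcodes, n_reads = n_reads),
    class = "read_sim_params")
}

# Barcode sets must be pairwise non-substring (in either orientation) so that
# presence-based demultiplexing cannot be ambiguous.
check_barcode_set <- function(bcs) {
  bcs <- toupper(bcs)
  if (anyDuplicated(bcs)) stop_param("duplicate barcodes in set")
  n <- length(bcs)
  if (n < 2) return(invisible(TRUE))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(bcs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && grepl(bcs[i], bcs[j], fixed = TRUE))
      stop_param("barcode set is not substring-free")
    if (grepl(bcs[i], rc[j], fixed = TRUE))
      stop_param("barcode set is not substring-free under reverse complement")
  }
  invisible(TRUE)
}

#' Describe one amplicon target locus
#'
#' @param gene gene name.
#' @param wt_reference wild-type amplicon sequence (interior of the amplicon,
#'   without barcodes).
#' @param cut_position 0-based position on `wt_reference` at which the
#'   nuclease cuts and the tag is inserted.
#' @param tag_sequence tag coding sequence inserted by HDR (48 nt by
#'   default).
#' @param linker_sequence linker placed before the tag (9-nt triple glycine
#'   by default).
#' @param gene_barcodes character vector of the two gene-specific barcodes.
#' @param indel_window_bp half-width of the window around `cut_position`
#'   within which indels are counted as edits.
#' @return An object of class `target_spec`. The knock-in reference
#'   (`hdr_reference`) is the wild-type sequence with `linker+tag` inserted
#'   at `cut_position`.
#' @export
target_spec <- function(gene, wt_reference, cut_position,
                        tag_sequence = default_tag_sequence(),
                        linker_sequence = default_linker_sequence(),
                        gene_barcodes, indel_window_bp = 10) {
  wt_reference <- toupper(wt_reference)
  tag_sequence <- toupper(tag_sequence)
  linker_sequence <- toupper(linker_sequence)
  if (!nzchar(wt_reference)) stop_param("empty wild-type reference")
  if (cut_position < 0 || cut_position > nchar(wt_reference))
    stop_param("'cut_position' outside the wild-type reference")
  if (length(gene_barcodes) != 2) stop_param("need exactly two gene barcodes")
  insert <- paste0(linker_sequence, tag_sequence)
  hdr <- paste0(substr(wt_reference, 1, cut_position), insert,
                substr(wt_reference, cut_position + 1, nchar(wt_reference)))
  structure(list(
    gene = gene, wt_reference = wt_reference, hdr_reference = hdr,
    cut_position = as.integer(cut_position),
    tag_sequence = tag_sequence, linker_sequence = linker_sequence,
    insert_start = as.integer(cut_position),       # 0-based, on hdr_reference
    insert_length = nchar(insert),
    gene_barcodes = toupper(gene_barcodes),
    indel_window_bp = as.integer(indel_window_bp)), class = "target_spec")
}

#' Generate a synthetic target locus
#'
#' Draws a random wild-type amplicon and two gene barcodes; used for tests
#' and simulations when no real locus table is supplied.
#'
#' @param gene gene name for the synthetic locus.
#' @param amplicon_length length of the wild-type amplicon interior (nt).
#' @param barcode_length barcode length (nt).
#' @param seed RNG seed.
#' @inheritParams target_spec
#' @return A `target_spec` object.
#' @export
synthetic_target <- function(gene = "GENE1", amplicon_length = 240,
                             barcode_length = 12, seed = 20,
                             indel_window_bp = 10) {
  with_seed(seed, {
    wt <- paste(sample(c("A", "C", "G", "T"), amplicon_length, TRUE),
                collapse = "")
    bcs <- make_barcodes(2, barcode_length)
    target_spec(gene = gene, wt_reference = wt,
                cut_position = round(amplicon_length / 2),
                gene_barcodes = bcs, indel_window_bp = indel_window_bp)
  })
}

#' Draw a substring-free barcode set
#'
#' Samples random DNA barcodes, rejecting candidates that contain (or are
#' contained in) an already accepted barcode in either orientation.
#'
#' @param n number of barcodes.
#' @param length barcode length (nt).
#' @return Character vector of `n` barcodes. Uses the current RNG stream;
#'   wrap in a seeded context for reproducibility.
#' @export
make_barcodes <- function(n, length = 12) {
  out <- character(0)
  tries <- 0
  while (base::length(out) < n) {
    tries <- tries + 1
    if (tries > 1000 * n) stop_param("failed to draw a substring-free barcode set")
    cand <- paste(sample(c("A", "C", "G", "T"), length, TRUE), collapse = "")
    ok <- tryCatch({ check_barcode_set(c(out, cand)); TRUE },
                   error = function(e) FALSE)
    if (ok) out <- c(out, cand)
  }
  out
}
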