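# Batch drivers and file plumbing binding the modules together. Each
# run_*() function takes a configuration (a named list, or a YAML/JSON file
# path), writes CSV/JSON outputs at fixed precision, and returns the output
# paths invisibly. A thin command-line wrapper around these functions is
# installed under inst/cli/.

#' Load a run configuration
#'
#' @param config a named list, or a path to a YAML or JSON file.
#' @return The configuration as a named list.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_param("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_param("'config' must be a list or file path")
  config
}

write_provenance <- function(path, config, seed, extra = list()) {
  prov <- c(list(package = "knockintools",
                 version = as.character(utils::packageVersion("knockintools")),
                 seed = seed,
                 config = config), extra)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  path
}

write_csv_stable <- function(df, path, digits = 8) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], fmt_num, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

ensure_outdir <- function(out_dir) {
  if (is.null(out_dir)) stop_param("'out_dir' is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' Write and read target locus tables
#'
#' Targets round-trip through a FASTA of wild-type references plus a CSV of
#' per-gene metadata (cut position, barcodes, tag and linker sequences).
#'
#' @param targets list of [target_spec()] objects.
#' @param fasta_path,csv_path output paths.
#' @return The paths, invisibly.
#' @export
write_targets <- function(targets, fasta_path, csv_path) {
  wt <- Biostrings::DNAStringSet(vapply(targets, `[[`, "", "wt_reference"))
  names(wt) <- vapply(targets, `[[`, "", "gene")
  Biostrings::writeXStringSet(wt, fasta_path)
  df <- do.call(rbind, lapply(targets, function(tg)
    data.frame(gene = tg$gene, cut_position = tg$cut_position,
               barcode_fwd = tg$gene_barcodes[1],
               barcode_rev = tg$gene_barcodes[2],
               tag_sequence = tg$tag_sequence,
               linker_sequence = tg$linker_sequence,
               indel_window_bp = tg$indel_window_bp,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(fasta_path, csv_path))
}

#' @rdname write_targets
#' @export
read_targets <- function(fasta_path, csv_path) {
  wt <- Biostrings::readDNAStringSet(fasta_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    g <- df$gene[i]
    if (!g %in% names(wt)) stop_param("no reference for gene ", g)
    target_spec(gene = g, wt_reference = as.character(wt[[g]]),
                cut_position = df$cut_position[i],
                tag_sequence = df$tag_sequence[i],
                linker_sequence = df$linker_sequence[i],
                gene_barcodes = c(df$barcode_fwd[i], df$barcode_rev[i]),
                indel_window_bp = df$indel_window_bp[i])
  })
}

#' Run the simulators and write data plus ground truth
#'
#' Configuration fields: `what` (any of `"movie"`, `"plate"`, `"reads"`),
#' `out_dir`, `seed`, and optional `movie`, `plate`, `reads` sublists of
#' parameter overrides for [cell_sim_params()], [plate_sim_params()] and
#' [read_sim_params()].
#'
#' @param config list or YAML/JSON path (see [load_config()]).
#' @return Named vector of output paths, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- load_config(config)
  out <- ensure_outdir(cfg$out_dir)
  seed <- cfg$seed %||% 1
  what <- cfg$what %||% c("movie", "plate", "reads")
  paths <- character(0)
  if ("movie" %in% what) {
    p <- do.call(cell_sim_params, cfg$movie %||% list())
    sim <- simulate_division_movie(p, seed)
    tif <- file.path(out, "movie.tif")
    write_stack_tiff(sim$stack, tif)
    tr <- sim$truth
    truth <- list(furrow_width_um = round(tr$furrow_width_um, 8),
                  band_fwhm_um = tr$band_fwhm_um,
                  cortical_ratio = tr$cortical_ratio,
                  anaphase_onset_frame = tr$anaphase_onset_frame,
                  accumulation_onset_frame = tr$accumulation_onset_frame,
                  furrow_onset_frame = tr$furrow_onset_frame,
                  closure_frame = tr$closure_frame,
                  rule_onset_frame = tr$rule_onset_frame,
                  rule_completion_frame = tr$rule_completion_frame,
                  rule_duration_min = tr$rule_duration_min)
    jsonlite::write_json(truth, file.path(out, "movie_truth.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    paths <- c(paths, movie = tif,
               movie_truth = file.path(out, "movie_truth.json"))
  }
  if ("plate" %in% what) {
    p <- do.call(plate_sim_params, cfg$plate %||% list())
    sim <- simulate_plate_montage(p, seed)
    pdir <- file.path(out, "plate")
    if (!dir.exists(pdir)) dir.create(pdir)
    layout <- do.call(rbind, lapply(sim$wells, function(w) {
      f <- file.path(pdir, paste0(w$well_id, ".tif"))
      tiff::writeTIFF(w$image / max(w$image), f, bits.per.sample = 32)
      data.frame(well_id = w$well_id, file = basename(f),
                 center_x = w$well_center_px[1],
                 center_y = w$well_center_px[2],
                 radius = w$well_radius_px, scale = max(w$image),
                 stringsAsFactors = FALSE)
    }))
    write_csv_stable(layout, file.path(out, "plate_layout.csv"))
    write_csv_stable(sim$truth, file.path(out, "plate_truth.csv"))
    paths <- c(paths, plate_layout = file.path(out, "plate_layout.csv"),
               plate_truth = file.path(out, "plate_truth.csv"))
  }
  if ("reads" %in% what) {
    p <- do.call(read_sim_params, cfg$reads %||% list())
    sim <- simulate_amplicon_reads(p, seed)
    fq <- file.path(out, "reads.fastq")
    write_fastq(sim$reads, fq)
    write_csv_stable(sim$truth, file.path(out, "reads_truth.csv"))
    write_targets(p$targets, file.path(out, "references.fasta"),
                  file.path(out, "targets.csv"))
    paths <- c(paths, reads = fq,
               reads_truth = file.path(out, "reads_truth.csv"),
               references = file.path(out, "references.fasta"),
               targets = file.path(out, "targets.csv"))
  }
  write_provenance(file.path(out, "simulate_provenance.json"), cfg, seed)
  invisible(paths)
}

#' Run the cytokinesis quantification pipeline on a movie file
#'
#' Configuration fields: `movie` (TIFF written by [write_stack_tiff()]),
#' `anaphase_onset_frame`, `out_dir`, and optional pipeline settings
#' (`inset_px`, `line_width_px`, `bleach_correct`).
#'
#' @param config list or YAML/JSON path.
#' @return Named vector of output paths, invisibly.
#' @export
run_quantify <- function(config) {
  cfg <- load_config(config)
  out <- ensure_outdir(cfg$out_dir)
  if (is.null(cfg$movie)) stop_param("'movie' input path is required")
  stack <- read_stack_tiff(cfg$movie)
  if (is.null(cfg$anaphase_onset_frame))
    stop_param("'anaphase_onset_frame' is required")
  q <- quantify_movie(stack, cfg$anaphase_onset_frame,
                      inset_px = cfg$inset_px %||% 3,
                      line_width_px = cfg$line_width_px %||% 5,
                      bleach_correct = cfg$bleach_correct %||% TRUE)
  write_csv_stable(q$results, file.path(out, "furrow_trace.csv"))
  if (!is.null(q$breadth))
    write_csv_stable(q$breadth, file.path(out, "breadth.csv"))
  summary <- list(
    duration_min = q$trace$duration_min,
    furrow_onset_frame = q$trace$furrow_onset_frame,
    completion_frame = q$trace$completion_frame,
    accumulation_onset_min =
      if (is.null(q$accumulation)) NULL else q$accumulation$onset_min,
    breadth_um = if (is.null(q$breadth) || !nrow(q$breadth)) NULL
                 else q$breadth$breadth_um[1])
  jsonlite::write_json(summary, file.path(out, "quantify_summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  write_provenance(file.path(out, "quantify_provenance.json"), cfg,
                   cfg$seed %||% NA)
  invisible(c(trace = file.path(out, "furrow_trace.csv"),
              summary = file.path(out, "quantify_summary.json")))
}

#' Run the colony screen on a plate directory
#'
#' Configuration fields: `plate_dir` (well TIFFs), `layout`
#' (plate-layout CSV as written by [run_simulate()]), `out_dir`, optional
#' detector settings (`blur_sigma_px`, `threshold_k`, `min_colony_area_px`,
#' `debris_tolerance`) and `qc_overlays` (write PNG overlays).
#'
#' @param config list or YAML/JSON path.
#' @return Named vector of output paths, invisibly.
#' @export
run_screen_plate <- function(config) {
  cfg <- load_config(config)
  out <- ensure_outdir(cfg$out_dir)
  layout <- utils::read.csv(cfg$layout, stringsAsFactors = FALSE)
  if (anyDuplicated(layout$well_id)) stop_param("duplicate well_ids in layout")
  wells <- lapply(seq_len(nrow(layout)), function(i) {
    f <- file.path(cfg$plate_dir, layout$file[i])
    if (!file.exists(f)) stop_param("missing well image: ", layout$file[i])
    img <- tiff::readTIFF(f) * (layout$scale[i] %||% 1)
    structure(list(well_id = layout$well_id[i], image = img,
                   well_center_px = c(layout$center_x[i], layout$center_y[i]),
                   well_radius_px = layout$radius[i]), class = "well_image")
  })
  scr <- screen_plate(wells,
                      blur_sigma_px = cfg$blur_sigma_px %||% 4,
                      threshold_k = cfg$threshold_k %||% 3,
                      min_colony_area_px = cfg$min_colony_area_px %||% 300,
                      debris_tolerance = cfg$debris_tolerance %||% 0)
  write_csv_stable(scr$records, file.path(out, "well_records.csv"))
  jsonlite::write_json(scr$summary, file.path(out, "screen_summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (isTRUE(cfg$qc_overlays)) {
    qdir <- file.path(out, "qc")
    if (!dir.exists(qdir)) dir.create(qdir)
    for (i in seq_along(wells)) write_qc_overlay(
      wells[[i]], scr$outlines[[i]],
      file.path(qdir, paste0(wells[[i]]$well_id, ".png")))
  }
  write_provenance(file.path(out, "screen_provenance.json"), cfg,
                   cfg$seed %||% NA)
  invisible(c(records = file.path(out, "well_records.csv"),
              summary = file.path(out, "screen_summary.json")))
}

# QC overlay: normalized well image with detected outlines burned in white.
write_qc_overlay <- function(well, outlines, path) {
  img <- well$image / max(well$image)
  for (o in outlines) {
    idx <- cbind(round(o[, "y"]) + 1, round(o[, "x"]) + 1)
    ok <- idx[, 1] >= 1 & idx[, 1] <= nrow(img) &
      idx[, 2] >= 1 & idx[, 2] <= ncol(img)
    img[idx[ok, , drop = FALSE]] <- 1
  }
  grDevices::png(path, width = ncol(img), height = nrow(img))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                  axes = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  path
}

#' Run amplicon genotyping on a FASTQ file
#'
#' Configuration fields: `fastq`, `references` (FASTA) + `targets` (CSV)
#' as written by [write_targets()], `mode` (`"population"` or `"clone"`),
#' optional `clone_barcodes` (named list), `min_q`, `max_mismatch`,
#' `with_indels`, classification settings, and `out_dir`.
#'
#' @param config list or YAML/JSON path.
#' @return Named vector of output paths, invisibly.
#' @export
run_genotype <- function(config) {
  cfg <- load_config(config)
  out <- ensure_outdir(cfg$out_dir)
  reads <- read_fastq(cfg$fastq)
  targets <- read_targets(cfg$references, cfg$targets)
  mode <- cfg$mode %||% "population"
  clone_bcs <- if (!is.null(cfg$clone_barcodes)) unlist(cfg$clone_barcodes)
  n_input <- nrow(reads)
  kept <- filter_reads(reads, min_q = cfg$min_q %||% 10)
  dmx <- demultiplex(kept, targets, mode = mode, clone_barcodes = clone_bcs,
                     max_mismatch = cfg$max_mismatch %||% 0,
                     with_indels = cfg$with_indels %||% FALSE)
  calls_all <- list(); freq_rows <- list(); clone_rows <- list()
  for (bin in names(dmx$bins)) {
    idx <- dmx$bins[[bin]]
    gene <- strsplit(bin, "/", fixed = TRUE)[[1]][1]
    tg <- targets[[which(vapply(targets, `[[`, "", "gene") == gene)]]
    cl <- classify_reads(kept[idx, , drop = FALSE], tg, mode = mode,
                         tag_mismatch_max = cfg$tag_mismatch_max %||% 2,
                         indel_min_size = cfg$indel_min_size %||% 2)
    cl <- cbind(data.frame(id = kept$id[idx], bin = bin,
                           stringsAsFactors = FALSE), cl)
    calls_all[[bin]] <- cl
    pf <- population_frequencies(cl$class)
    freq_rows[[bin]] <- data.frame(
      bin = bin, n_reads = pf$n_reads, n_ambiguous = pf$n_ambiguous,
      wt = pf$fractions[["WT"]], indel = pf$fractions[["INDEL"]],
      hdr = pf$fractions[["HDR"]], stringsAsFactors = FALSE)
    if (mode == "clone") {
      gt <- call_clone_genotype(cl$class,
                                min_allele_fraction =
                                  cfg$min_allele_fraction %||% 0.2,
                                min_reads = cfg$min_reads %||% 50)
      clone_rows[[bin]] <- data.frame(
        bin = bin, zygosity = gt$zygosity,
        allele1 = gt$alleles[1], allele2 = gt$alleles[2],
        n_reads = gt$n_reads, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls_all)
  write_csv_stable(calls, file.path(out, "read_calls.csv"))
  write_csv_stable(do.call(rbind, freq_rows),
                   file.path(out, "allele_frequencies.csv"))
  if (length(clone_rows))
    write_csv_stable(do.call(rbind, clone_rows),
                     file.path(out, "clone_genotypes.csv"))
  conservation <- list(n_input = n_input, n_low_q = n_input - nrow(kept),
                       n_unassigned = length(dmx$unassigned),
                       n_assigned = sum(lengths(dmx$bins)))
  jsonlite::write_json(conservation, file.path(out, "genotype_summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write_provenance(file.path(out, "genotype_provenance.json"), cfg,
                   cfg$seed %||% NA)
  invisible(c(calls = file.path(out, "read_calls.csv"),
              frequencies = file.path(out, "allele_frequencies.csv"),
              summary = file.path(out, "genotype_summary.json")))
}
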