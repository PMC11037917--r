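# Synthetic Nanopore-style amplicon reads: barcoded allele sequences with a
# per-base error model (substitutions and short indels), per-base Phred
# qualities, random orientation, and a per-read ground-truth table.

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))

# Construct one allele sequence for a target.
make_allele <- function(target, class, indel_sizes, indel_probs,
                        tag_mutations) {
  wt <- target$wt_reference; hdr <- target$hdr_reference
  cut <- target$cut_position
  if (class == "WT") return(list(seq = wt, detail = ""))
  if (class == "HDR") return(list(seq = hdr, detail = ""))
  if (class == "HDR_MUTANT") {
    k <- sample(seq(tag_mutations[1], tag_mutations[2]), 1)
    tag_start <- target$insert_start + nchar(target$linker_sequence) + 1
    pos <- sample(seq(tag_start, target$insert_start + target$insert_length),
                  k)
    ch <- strsplit(hdr, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    return(list(seq = paste(ch, collapse = ""),
                detail = sprintf("tag_subs=%d", k)))
  }
  if (class == "INDEL") {
    s <- indel_sizes[sample.int(length(indel_sizes), 1, prob = indel_probs)]
    if (s < 0) {
      del <- min(-s, nchar(wt) - cut)
      seq <- paste0(substr(wt, 1, cut), substr(wt, cut + del + 1, nchar(wt)))
      return(list(seq = seq, detail = sprintf("del=%d", del)))
    }
    ins <- paste(sample(DNA_BASES, s, TRUE), collapse = "")
    seq <- paste0(substr(wt, 1, cut), ins, substr(wt, cut + 1, nchar(wt)))
    return(list(seq = seq, detail = sprintf("ins=%d", s)))
  }
  stop_param("unknown allele class")
}

# Apply per-base sequencing errors (80% substitutions, 10% insertions,
# 10% deletions of the total rate).
apply_read_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (!length(hit)) return(seq)
  type <- sample(c("sub", "ins", "del"), length(hit), TRUE,
                 prob = c(0.8, 0.1, 0.1))
  del <- logical(length(ch))
  for (i in seq_along(hit)) {
    p <- hit[i]
    if (type[i] == "sub") ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    else if (type[i] == "ins") ch[p] <- paste0(ch[p], sample(DNA_BASES, 1))
    else del[p] <- TRUE
  }
  paste(ch[!del], collapse = "")
}

phred_string <- function(q) intToUtf8(pmin(pmax(round(q), 2), 41) + 33)

#' Mean read quality from a Sanger-encoded quality string
#'
#' The read-level Q score is the Phred transform of the mean per-base error
#' probability: `-10 * log10(mean(10^(-q/10)))`.
#'
#' @param quality character vector of Sanger (offset 33) quality strings.
#' @return Numeric vector of read-level Q scores.
#' @export
read_mean_q <- function(quality) {
  vapply(quality, function(q) {
    if (!nzchar(q)) return(0)
    p <- 10^(-(utf8ToInt(q) - 33) / 10)
    -10 * log10(mean(p))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Simulate barcoded amplicon reads
#'
#' Draws each read's source allele from the requested mixture, assembles the
#' barcoded amplicon (`gene_bc1 + allele + revcomp(gene_bc2)`, flanked by a
#' clone barcode pair when `clone_barcodes` are supplied), applies per-base
#' substitution/indel errors, random orientation and per-base qualities, and
#' returns the reads with a per-read truth table.
#'
#' @param params a [read_sim_params()].
#' @param seed integer seed.
#' @return A list with:
#'   \describe{
#'     \item{reads}{data frame `id`, `sequence`, `quality`, `mean_q`.}
#'     \item{truth}{data frame `id`, `gene`, `clone`, `class`, `detail`,
#'       `orientation`.}
#'   }
#' @export
simulate_amplicon_reads <- function(params = read_sim_params(), seed = 1) {
  if (!inherits(params, "read_sim_params"))
    stop_param("'params' must come from read_sim_params()")
  p <- params
  for (tg in p$targets)
    if (!nzchar(tg$wt_reference)) stop_param("empty reference")
  sizes <- as.integer(names(p$indel_size_distribution))
  with_seed(derive_seed(seed, 6), {
    n <- p$n_reads
    tgt_idx <- sample.int(length(p$targets), n, replace = TRUE)
    classes <- names(p$allele_mixture)[
      sample.int(4, n, replace = TRUE, prob = p$allele_mixture)]
    clones <- if (is.null(p$clone_barcodes)) rep(NA_character_, n)
              else sample(names(p$clone_barcodes), n, replace = TRUE)
    flip <- stats::runif(n) < 0.5
    # orientation flips are applied in one vectorized pass at the end
    gbc2_rc <- lapply(p$targets, function(tg) revcomp(tg$gene_barcodes[2]))
    cbc_rc <- if (is.null(p$clone_barcodes)) NULL
              else stats::setNames(revcomp(unname(p$clone_barcodes)),
                                   names(p$clone_barcodes))
    seqs <- character(n); detail <- character(n)
    for (i in seq_len(n)) {
      tg <- p$targets[[tgt_idx[i]]]
      al <- make_allele(tg, classes[i], sizes, p$indel_size_distribution,
                        p$tag_mutations)
      detail[i] <- al$detail
      s <- paste0(tg$gene_barcodes[1], al$seq, gbc2_rc[[tgt_idx[i]]])
      if (!is.na(clones[i])) {
        cb <- p$clone_barcodes[[clones[i]]]
        s <- paste0(cb, s, cbc_rc[[clones[i]]])
      }
      seqs[i] <- apply_read_errors(s, p$per_base_error_rate)
    }
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    quals <- vapply(nchar(seqs), function(L)
      phred_string(stats::rnorm(L, p$mean_q, p$sd_q)), character(1))
    ids <- sprintf("read%06d", seq_len(n))
    reads <- data.frame(id = ids, sequence = seqs, quality = quals,
                        mean_q = read_mean_q(quals),
                        stringsAsFactors = FALSE)
    truth <- data.frame(
      id = ids, gene = vapply(p$targets[tgt_idx], `[[`, "", "gene"),
      clone = clones, class = classes, detail = detail,
      orientation = ifelse(flip, "reverse", "forward"),
      stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Write reads as FASTQ (Sanger qualities)
#'
#' @param reads data frame with `id`, `sequence`, `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  q <- Biostrings::PhredQuality(reads$quality)
  # suppress the harmless note about dropped (empty) metadata columns
  suppressWarnings({
    xq <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(xq, path)
  })
  invisible(path)
}

#' Read a FASTQ file into the package's read table
#'
#' @param path FASTQ path (Sanger quality encoding).
#' @return Data frame with `id`, `sequence`, `quality`, `mean_q`.
#' @export
read_fastq <- function(path) {
  # Biostrings notes that (empty) metadata columns are dropped; harmless
  xq <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(xq),
             sequence = as.character(xq),
             quality = as.character(Biostrings::quality(xq)),
             mean_q = read_mean_q(as.character(Biostrings::quality(xq))),
             stringsAsFactors = FALSE)
}
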