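# Amplicon genotyping: read-level quality filtering, presence-based
# dual-barcode demultiplexing, semi-global alignment of each read to the
# wild-type and knock-in references, allele classification
# (WT / INDEL / HDR / HDR_MUTANT / AMBIGUOUS), population allele
# frequencies and diploid clone genotype calls.

ALLELE_CLASSES <- c("WT", "INDEL", "HDR", "HDR_MUTANT", "AMBIGUOUS")

#' Filter reads on mean quality
#'
#' Removes reads whose read-level Q score (Phred transform of the mean
#' per-base error probability) is strictly below `min_q`; a read at exactly
#' `min_q` is retained.
#'
#' @param reads data frame with `sequence` and `quality` (and optionally a
#'   precomputed `mean_q`).
#' @param min_q minimum mean Q score (default 10).
#' @return The retained rows of `reads`, with `mean_q` filled in.
#' @export
filter_reads <- function(reads, min_q = 10) {
  if (nrow(reads) == 0) return(reads)
  if (is.null(reads$quality) || any(!nzchar(reads$quality)))
    stop_param("reads are missing quality strings")
  if (is.null(reads$mean_q)) reads$mean_q <- read_mean_q(reads$quality)
  reads[reads$mean_q >= min_q, , drop = FALSE]
}

# Presence of a barcode in reads, in either orientation.
barcode_hits <- function(seqs, rcs, barcode, max_mismatch, with_indels) {
  f <- Biostrings::vcountPattern(barcode, seqs, max.mismatch = max_mismatch,
                                 with.indels = with_indels) > 0
  r <- Biostrings::vcountPattern(barcode, rcs, max.mismatch = max_mismatch,
                                 with.indels = with_indels) > 0
  f | r
}

#' Demultiplex reads by barcode presence
#'
#' Scans each read (both orientations) for the gene-specific barcodes of
#' every target and, in clone mode, for clone-specific barcodes. Population
#' mode assigns a read on a hit to either of a target's two gene barcodes;
#' clone mode requires both a gene-barcode hit and a clone-barcode hit.
#' Reads hitting more than one target (or clone) are left unassigned.
#'
#' @param reads data frame with `sequence`.
#' @param targets list of [target_spec()] objects.
#' @param mode `"population"` or `"clone"`.
#' @param clone_barcodes named character vector of clone barcodes (clone
#'   mode).
#' @param max_mismatch allowed mismatches in a barcode hit (default 0,
#'   exact).
#' @param with_indels allow indels in barcode hits.
#' @return A list with `assignments` (data frame `id`, `gene`, `clone`,
#'   `assigned`), `bins` (a named list mapping `gene` or `gene/clone` to row
#'   indices of `reads`), `unassigned` (row indices) and `counts`.
#' @export
demultiplex <- function(reads, targets, mode = c("population", "clone"),
                        clone_barcodes = NULL, max_mismatch = 0,
                        with_indels = FALSE) {
  mode <- match.arg(mode)
  if (mode == "clone" && is.null(clone_barcodes))
    stop_param("clone mode requires 'clone_barcodes'")
  gene_bcs <- lapply(targets, `[[`, "gene_barcodes")
  names(gene_bcs) <- vapply(targets, `[[`, "", "gene")
  check_barcode_set(c(unlist(gene_bcs), clone_barcodes))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  rcs <- Biostrings::reverseComplement(seqs)

  gene_hit <- sapply(gene_bcs, function(bcs) {
    barcode_hits(seqs, rcs, bcs[1], max_mismatch, with_indels) |
      barcode_hits(seqs, rcs, bcs[2], max_mismatch, with_indels)
  })
  gene_hit <- matrix(gene_hit, nrow = nrow(reads),
                     dimnames = list(NULL, names(gene_bcs)))
  n_gene <- rowSums(gene_hit)
  gene <- rep(NA_character_, nrow(reads))
  one <- n_gene == 1
  gene[one] <- colnames(gene_hit)[max.col(gene_hit[one, , drop = FALSE])]

  clone <- rep(NA_character_, nrow(reads))
  if (mode == "clone") {
    clone_hit <- sapply(clone_barcodes, function(bc)
      barcode_hits(seqs, rcs, bc, max_mismatch, with_indels))
    clone_hit <- matrix(clone_hit, nrow = nrow(reads),
                        dimnames = list(NULL, names(clone_barcodes)))
    n_clone <- rowSums(clone_hit)
    onec <- n_clone == 1
    clone[onec] <- colnames(clone_hit)[max.col(clone_hit[onec, , drop = FALSE])]
    assigned <- one & onec
  } else {
    assigned <- one
  }
  key <- ifelse(assigned,
                if (mode == "clone") paste(gene, clone, sep = "/") else gene,
                NA_character_)
  bins <- split(which(assigned), key[assigned])
  list(assignments = data.frame(id = reads$id, gene = gene, clone = clone,
                                assigned = assigned,
                                stringsAsFactors = FALSE),
       bins = bins,
       unassigned = which(!assigned),
       counts = c(vapply(bins, length, 0L),
                  unassigned = sum(!assigned)))
}

# Vectorized per-read edit summaries from a PairwiseAlignments object.
# indel() ranges are in alignment-column space; a column c maps to subject
# position subject_start - 1 + c - (total insertion width at columns < c).
alignment_edits <- function(a) {
  ii <- Biostrings::indel(a)
  ins <- Biostrings::insertion(ii)
  del <- Biostrings::deletion(ii)
  n_ins <- S4Vectors::elementNROWS(ins)
  n_del <- S4Vectors::elementNROWS(del)
  ins_u <- unlist(ins); del_u <- unlist(del)
  s_start <- IRanges::start(Biostrings::subject(a))
  s_end <- IRanges::end(Biostrings::subject(a))
  ins_read <- rep(seq_along(n_ins), n_ins)
  del_read <- rep(seq_along(n_del), n_del)
  ins_start <- IRanges::start(ins_u); ins_w <- IRanges::width(ins_u)
  del_start <- IRanges::start(del_u); del_w <- IRanges::width(del_u)
  # insertion width accumulated before a given column, per read
  ins_before <- function(read, col) {
    out <- numeric(length(read))
    for (j in seq_along(read)) {
      sel <- ins_read == read[j] & ins_start < col[j]
      if (any(sel)) out[j] <- sum(ins_w[sel])
    }
    out
  }
  del_sub_start <- s_start[del_read] - 1 + del_start -
    ins_before(del_read, del_start)
  ins_sub_pos <- s_start[ins_read] - 1 + ins_start -
    ins_before(ins_read, ins_start) - 1
  mt <- Biostrings::mismatchTable(a)
  list(n = length(a),
       s_start = s_start, s_end = s_end,
       sub_read = mt$PatternId, sub_pos = mt$SubjectStart,
       del_read = del_read, del_start = del_sub_start,
       del_end = del_sub_start + del_w - 1, del_w = del_w,
       ins_read = ins_read, ins_pos = ins_sub_pos, ins_w = ins_w)
}

count_in_range <- function(read, pos, lo, hi, n) {
  sel <- pos >= lo & pos <= hi
  tabulate(read[sel], nbins = n)
}

#' Classify reads against a target's references
#'
#' Aligns each read (best orientation) to the wild-type and knock-in
#' references with semi-global, affine-gap alignment. A read whose
#' alignment favours the knock-in reference is `HDR` when the full-length
#' tag insertion is present with at most `tag_mismatch_max` substitutions
#' and no internal indels, and `HDR_MUTANT` otherwise; in population mode
#' both are reported as `HDR`. A read favouring the wild-type reference is
#' `INDEL` when its summed insertion or deletion gap width overlapping
#' `cut_position +/- indel_window_bp` reaches `indel_min_size` bases,
#' and `WT` otherwise. Reads shorter than twice the barcode length, or
#' whose best alignment score normalized by the reference length falls
#' below `min_norm_score`, are `AMBIGUOUS`.
#'
#' @param reads data frame with `sequence` (rows already demultiplexed to
#'   this target).
#' @param target a [target_spec()].
#' @param mode `"population"` merges `HDR_MUTANT` into `HDR`; `"clone"`
#'   keeps them distinct.
#' @param tag_mismatch_max maximum substitutions inside the tag for an
#'   intact `HDR` call (clone mode).
#' @param indel_window_bp window half-width around the cut site.
#' @param indel_min_size minimum contiguous indel run (bases) treated as an
#'   edit rather than sequencing noise.
#' @param min_norm_score minimum of `score / (match * reference length)`
#'   for a classifiable read.
#' @param match,mismatch,gap_opening,gap_extension alignment scoring.
#' @return Data frame, one row per read: `class`, `score_wt`, `score_hdr`,
#'   `tag_mismatches`, `tag_indel`, `indel_size`, `norm_score`.
#' @export
classify_reads <- function(reads, target, mode = c("population", "clone"),
                           tag_mismatch_max = 2, indel_window_bp = NULL,
                           indel_min_size = 2, min_norm_score = 0.5,
                           match = 2, mismatch = -4,
                           gap_opening = 6, gap_extension = 2) {
  mode <- match.arg(mode)
  empty <- data.frame(class = character(0), score_wt = numeric(0),
                      score_hdr = numeric(0), tag_mismatches = integer(0),
                      tag_indel = logical(0), indel_size = integer(0),
                      norm_score = numeric(0))
  if (nrow(reads) == 0) return(empty)
  indel_window_bp <- indel_window_bp %||% target$indel_window_bp
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  wt <- Biostrings::DNAString(target$wt_reference)
  hdr <- Biostrings::DNAString(target$hdr_reference)
  seqs <- Biostrings::DNAStringSet(toupper(reads$sequence))
  rcs <- Biostrings::reverseComplement(seqs)
  aln <- function(pat, ref, score_only)
    Biostrings::pairwiseAlignment(pat, ref, type = "overlap",
                                  substitutionMatrix = mat,
                                  gapOpening = gap_opening,
                                  gapExtension = gap_extension,
                                  scoreOnly = score_only)
  s_wt_f <- aln(seqs, wt, TRUE); s_wt_r <- aln(rcs, wt, TRUE)
  s_hdr_f <- aln(seqs, hdr, TRUE); s_hdr_r <- aln(rcs, hdr, TRUE)
  use_rc <- pmax(s_wt_r, s_hdr_r) > pmax(s_wt_f, s_hdr_f)
  oriented <- seqs
  oriented[use_rc] <- rcs[use_rc]
  s_wt <- ifelse(use_rc, s_wt_r, s_wt_f)
  s_hdr <- ifelse(use_rc, s_hdr_r, s_hdr_f)

  n <- nrow(reads)
  is_hdr_side <- s_hdr > s_wt
  tag_start <- target$insert_start + nchar(target$linker_sequence) + 1
  tag_end <- target$insert_start + target$insert_length
  cut <- target$cut_position
  win <- c(cut - indel_window_bp + 1, cut + indel_window_bp)
  min_len <- 2 * max(nchar(target$gene_barcodes))
  norm_score <- ifelse(is_hdr_side,
                       s_hdr / (match * nchar(target$hdr_reference)),
                       s_wt / (match * nchar(target$wt_reference)))

  tag_mm <- integer(n); tag_indel <- logical(n); indel_sz <- integer(n)
  class <- rep("WT", n)

  if (any(is_hdr_side)) {
    ih <- which(is_hdr_side)
    e <- alignment_edits(aln(oriented[ih], hdr, FALSE))
    covered <- e$s_start <= tag_start & e$s_end >= tag_end
    mm <- count_in_range(e$sub_read, e$sub_pos, tag_start, tag_end, e$n)
    has_del <- rep(FALSE, e$n)
    sel <- e$del_start <= tag_end & e$del_end >= tag_start
    has_del[unique(e$del_read[sel])] <- TRUE
    has_ins <- rep(FALSE, e$n)
    sel <- e$ins_pos >= tag_start & e$ins_pos < tag_end
    has_ins[unique(e$ins_read[sel])] <- TRUE
    intact <- covered & !has_del & !has_ins & mm <= tag_mismatch_max
    tag_mm[ih] <- mm
    tag_indel[ih] <- !covered | has_del | has_ins
    class[ih] <- ifelse(intact | mode == "population", "HDR", "HDR_MUTANT")
  }
  if (any(!is_hdr_side)) {
    iw <- which(!is_hdr_side)
    e <- alignment_edits(aln(oriented[iw], wt, FALSE))
    # total gap width per type within the window; summing (rather than the
    # longest single run) keeps an edit that sequencing errors split into
    # two short gaps, while isolated single-base sequencing indels stay
    # below indel_min_size
    sz <- numeric(e$n)
    sel <- e$del_start <= win[2] & e$del_end >= win[1]
    if (any(sel)) {
      tot <- tapply(e$del_w[sel], e$del_read[sel], sum)
      sz[as.integer(names(tot))] <- pmax(sz[as.integer(names(tot))], tot)
    }
    sel <- e$ins_pos >= win[1] - 1 & e$ins_pos <= win[2]
    if (any(sel)) {
      tot <- tapply(e$ins_w[sel], e$ins_read[sel], sum)
      sz[as.integer(names(tot))] <- pmax(sz[as.integer(names(tot))], tot)
    }
    indel_sz[iw] <- as.integer(sz)
    class[iw] <- ifelse(sz >= indel_min_size, "INDEL", "WT")
  }
  too_short <- nchar(reads$sequence) < min_len
  class[too_short | norm_score < min_norm_score] <- "AMBIGUOUS"
  data.frame(class = class, score_wt = s_wt, score_hdr = s_hdr,
             tag_mismatches = tag_mm, tag_indel = tag_indel,
             indel_size = indel_sz, norm_score = norm_score,
             stringsAsFactors = FALSE)
}

#' @rdname classify_reads
#' @param read a single-row read data frame (or a list with `sequence`).
#' @param ... passed to [classify_reads()].
#' @export
classify_read <- function(read, target, ...) {
  df <- as.data.frame(read, stringsAsFactors = FALSE)
  classify_reads(df, target, ...)[1, ]
}

#' Population allele frequencies
#'
#' Fractions of `WT`, `INDEL` and `HDR` among classified (non-ambiguous)
#' reads; `HDR_MUTANT` calls are merged into `HDR`, matching population-mode
#' reporting. The ambiguous count is reported separately.
#'
#' @param calls character vector of classes, or the data frame from
#'   [classify_reads()].
#' @return An object of class `population_allele_freq`: `fractions` (named,
#'   summing to 1), `counts`, `n_reads`, `n_ambiguous`.
#' @export
population_frequencies <- function(calls) {
  cls <- if (is.data.frame(calls)) calls$class else as.character(calls)
  cls[cls == "HDR_MUTANT"] <- "HDR"
  n_amb <- sum(cls == "AMBIGUOUS")
  cls <- cls[cls != "AMBIGUOUS"]
  if (!length(cls)) stop_param("no classified (non-ambiguous) reads")
  counts <- table(factor(cls, levels = c("WT", "INDEL", "HDR")))
  structure(list(fractions = stats::setNames(as.numeric(counts) / length(cls),
                                             names(counts)),
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n_reads = length(cls), n_ambiguous = n_amb),
            class = "population_allele_freq")
}

#' @export
print.population_allele_freq <- function(x, ...) {
  cat(sprintf("allele frequencies over %d reads (%d ambiguous):\n",
              x$n_reads, x$n_ambiguous))
  for (k in names(x$fractions))
    cat(sprintf("  %-6s %6.2f%%\n", k, 100 * x$fractions[[k]]))
  invisible(x)
}

#' Call a diploid clone genotype from read-level classes
#'
#' Classes whose read fraction reaches `min_allele_fraction` are candidate
#' alleles: exactly one candidate gives a homozygous call (that allele
#' twice), exactly two a heterozygous call, anything else is ambiguous.
#' Below `min_reads` classified reads the call is ambiguous with a warning.
#'
#' @param calls character vector of classes or a [classify_reads()] data
#'   frame (clone mode, so `HDR_MUTANT` is kept distinct).
#' @param min_allele_fraction minimum read fraction for a candidate allele.
#' @param min_reads minimum number of classified reads for a confident
#'   call.
#' @return An object of class `clone_genotype`: `alleles` (two labels or
#'   `NA`), `zygosity` (`homozygous`, `heterozygous` or `ambiguous`) and the
#'   per-class `fractions`.
#' @export
call_clone_genotype <- function(calls, min_allele_fraction = 0.2,
                                min_reads = 50) {
  cls <- if (is.data.frame(calls)) calls$class else as.character(calls)
  n_amb <- sum(cls == "AMBIGUOUS")
  cls <- cls[cls != "AMBIGUOUS"]
  tab <- table(factor(cls, levels = setdiff(ALLELE_CLASSES, "AMBIGUOUS")))
  frac <- stats::setNames(as.numeric(tab) / max(length(cls), 1), names(tab))
  if (length(cls) < min_reads) {
    warning(sprintf("only %d classified reads (< %d); genotype ambiguous",
                    length(cls), min_reads))
    return(structure(list(alleles = c(NA_character_, NA_character_),
                          zygosity = "ambiguous", fractions = frac,
                          n_reads = length(cls), n_ambiguous = n_amb),
                     class = "clone_genotype"))
  }
  cand <- names(frac)[frac >= min_allele_fraction]
  if (length(cand) == 1) {
    res <- list(alleles = rep(cand, 2), zygosity = "homozygous")
  } else if (length(cand) == 2) {
    cand <- cand[order(-frac[cand])]
    res <- list(alleles = cand, zygosity = "heterozygous")
  } else {
    res <- list(alleles = c(NA_character_, NA_character_),
                zygosity = "ambiguous")
  }
  structure(c(res, list(fractions = frac, n_reads = length(cls),
                        n_ambiguous = n_amb)),
            class = "clone_genotype")
}

#' @export
print.clone_genotype <- function(x, ...) {
  cat(sprintf("clone genotype: %s", x$zygosity))
  if (!is.na(x$alleles[1]))
    cat(sprintf(" (%s / %s)", x$alleles[1], x$alleles[2]))
  cat(sprintf(" [%d reads]\n", x$n_reads))
  invisible(x)
}
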