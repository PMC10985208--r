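#' Excise candidate precursor windows around a read cluster
#'
#' For each window length and each of three anchorings of the most
#' abundant ("mature") read -- near the window start with a 15-nt flank,
#' centred, and near the window end with a 15-nt flank -- a genomic window
#' is cut out, clipped to the chromosome, and kept when it still spans at
#' least `min_window` nt and contains the mature read. Minus-strand
#' windows are reverse-complemented so the candidate sequence is the
#' transcribed strand, and read offsets are recomputed accordingly. All
#' cluster reads falling fully inside the window are attached.
#'
#' @param index a `genome_index`.
#' @param cluster one cluster from [cluster_loci()].
#' @param window_lengths candidate window lengths (nt); the defaults
#'   100/150/200 span the plant precursor length range.
#' @param flank minimum flank left around the mature read (nt).
#' @param min_window shortest window emitted after clipping.
#' @param cluster_id identifier attached to each candidate (used when
#'   deduplicating across windows).
#' @return a list of `precursor_candidate` objects: `chrom`, `strand`,
#'   `start`, `end` (0-based half-open genomic window), `sequence` (RNA,
#'   transcribed strand), `mapped_reads` (data.frame of `offset` (0-based,
#'   transcribed strand), `length`, `count`, `read_id`), `mature_span`
#'   (1-based within the window), `fold` (filled by
#'   [select_hairpin_candidates()]), `label`.
#' @export
extract_candidates <- function(index, cluster,
                               window_lengths = c(100L, 150L, 200L),
                               flank = 15L, min_window = 100L,
                               cluster_id = 1L) {
  loci <- cluster$loci
  if (is.null(loci) || nrow(loci) == 0) return(list())
  chrom <- cluster$chrom
  chrom_seq <- index$sequences[[chrom]]
  clen <- length(chrom_seq)

  # mature = most abundant member; ties resolved towards the transcribed
  # 5' end (genomic left on +, genomic right on -)
  best <- which(loci$count == max(loci$count))
  if (length(best) > 1) {
    best <- if (cluster$strand == "+") best[which.min(loci$start[best])]
            else best[which.max(loci$start[best])]
  }
  m_start <- loci$start[best]; m_end <- loci$end[best]

  wins <- list()
  # centre rounding is strand-aware so that a locus planted on either
  # strand yields mirror-identical windows
  mid <- (m_start + m_end + (cluster$strand == "-")) %/% 2L
  for (W in sort(as.integer(window_lengths))) {
    anchors <- c(m_start - flank,
                 mid - W %/% 2L,
                 m_end + flank - W)
    for (s in anchors) {
      ws <- max(0L, as.integer(s)); we <- min(clen, as.integer(s) + W)
      if (we - ws < min_window) next
      if (m_start < ws || m_end > we) next
      wins[[paste(ws, we)]] <- c(ws, we)
    }
  }
  if (length(wins) == 0) {
    message("cluster ", cluster_id, ": no valid window near contig end")
    return(list())
  }

  lapply(unname(wins), function(w) {
    ws <- w[1]; we <- w[2]
    inside <- loci$start >= ws & loci$end <= we
    rows <- loci[inside, , drop = FALSE]
    offs <- if (cluster$strand == "+") rows$start - ws else we - rows$end
    reads <- data.frame(offset = as.integer(offs),
                        length = rows$end - rows$start,
                        count = rows$count, read_id = rows$read_id,
                        stringsAsFactors = FALSE)
    reads <- reads[order(reads$offset, reads$read_id), , drop = FALSE]
    rownames(reads) <- NULL
    seg <- Biostrings::subseq(chrom_seq, ws + 1L, we)
    if (cluster$strand == "-") seg <- Biostrings::reverseComplement(seg)
    m_off <- if (cluster$strand == "+") m_start - ws else we - m_end
    structure(list(chrom = chrom, strand = cluster$strand,
                   start = ws, end = we,
                   sequence = chartr("T", "U", as.character(seg)),
                   mapped_reads = reads,
                   mature_span = c(m_off + 1L, m_off + (m_end - m_start)),
                   fold = NULL, label = "unlabeled",
                   cluster_id = cluster_id,
                   cluster_count = sum(loci$count)),
              class = "precursor_candidate")
  })
}

#' @export
print.precursor_candidate <- function(x, ...) {
  cat("precursor_candidate ", x$chrom, ":", x$start, "-", x$end, "(",
      x$strand, "), ", nchar(x$sequence), " nt, ",
      nrow(x$mapped_reads), " read(s), mature ", x$mature_span[1], "-",
      x$mature_span[2], ", label: ", x$label, "\n", sep = "")
  invisible(x)
}

#' Fold candidates and keep the best hairpin per cluster
#'
#' Folds every candidate (if not already folded), drops those failing
#' [is_hairpin()] on their mature span, and among the surviving windows of
#' each cluster keeps the single candidate with the most paired
#' mature-span bases (ties: shortest window, then leftmost). At most one
#' candidate per cluster survives, so overlapping windows cannot leak
#' between cross-validation folds.
#'
#' @param candidates list of `precursor_candidate` (possibly from several
#'   clusters).
#' @param min_paired_frac passed to [is_hairpin()].
#' @param min_loop passed to [fold_batch()].
#' @param fold_method `"mfe"`, `"nussinov"`, or `"auto"` (MFE via
#'   `RNAfold` when available, otherwise the built-in base-pair
#'   maximiser). MFE structures keep helix ends and flanks realistic,
#'   which the hairpin/duplex screens rely on; the Nussinov fallback is
#'   exact but pairs aggressively into flanking sequence.
#' @return the surviving candidates, folds filled in.
#' @export
select_hairpin_candidates <- function(candidates, min_paired_frac = 0.6,
                                      min_loop = 3L,
                                      fold_method = c("auto", "mfe",
                                                      "nussinov")) {
  fold_method <- match.arg(fold_method)
  if (fold_method == "auto")
    fold_method <- if (has_rnafold()) "mfe" else "nussinov"
  if (length(candidates) == 0) return(list())
  todo <- which(vapply(candidates, function(c) is.null(c$fold), TRUE))
  if (length(todo)) {
    folds <- fold_batch(vapply(candidates[todo], `[[`, "", "sequence"),
                        min_loop = min_loop, method = fold_method)
    for (i in seq_along(todo)) candidates[[todo[i]]]$fold <- folds[[i]]
  }
  scored <- lapply(candidates, function(cand) {
    hp <- is_hairpin(cand$fold, cand$mature_span, min_paired_frac)
    cand$hairpin <- hp$hairpin
    cand$mature_pairs <- hp$report$n_paired
    cand
  })
  keep <- Filter(function(cand) cand$hairpin, scored)
  if (length(keep) == 0) return(list())
  ids <- vapply(keep, `[[`, 1L, "cluster_id")
  out <- lapply(unique(ids), function(id) {
    group <- keep[ids == id]
    score <- vapply(group, `[[`, 0L, "mature_pairs")
    width <- vapply(group, function(c) c$end - c$start, 0L)
    left <- vapply(group, `[[`, 0L, "start")
    group[[order(-score, width, left)[1]]]
  })
  out
}

#' Write a candidate table as TSV
#'
#' One row per candidate: coordinates, strand, sequence, dot-bracket,
#' mature offset/length, label and a compact read list.
#'
#' @param candidates list of folded `precursor_candidate`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  rows <- lapply(candidates, function(x) {
    data.frame(chrom = x$chrom, start = x$start, end = x$end,
               strand = x$strand, sequence = x$sequence,
               dotbracket = if (is.null(x$fold)) "" else x$fold$dotbracket,
               mature_offset = x$mature_span[1] - 1L,
               mature_length = x$mature_span[2] - x$mature_span[1] + 1L,
               label = x$label,
               reads = paste(sprintf("%s:%d:%d:%d", x$mapped_reads$read_id,
                                     x$mapped_reads$offset,
                                     x$mapped_reads$length,
                                     x$mapped_reads$count), collapse = ","),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
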