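#' Run the full miRNA discovery pipeline
#'
#' Collapses and length-filters the reads, exact-matches them to both
#' genome strands, clusters mapped loci, excises candidate precursor
#' windows around each cluster, folds them, keeps the best single-stem
#' hairpin per cluster, and labels every surviving candidate with the
#' duplex criteria.
#'
#' @param genome genome FASTA path or [Biostrings::DNAStringSet].
#' @param reads read file path, or an already collapsed read data.frame.
#' @param format read file format, see [load_reads()].
#' @param min_len,max_len read length filter (default 20--24 nt).
#' @param k,max_hits,max_gap mapping/clustering parameters
#'   ([build_index()], [map_reads()], [cluster_loci()]).
#' @param window_lengths,flank extraction windows ([extract_candidates()]).
#' @param L encoded matrix width.
#' @param min_paired_frac hairpin screen ([is_hairpin()]).
#' @param min_duplex_fraction labelling rule ([label_candidate()]).
#' @param fold_method structure prediction method, see
#'   [select_hairpin_candidates()].
#' @param verbose print stage summaries.
#' @return a list: `reads` (collapsed, filtered), `loci` (mapped),
#'   `clusters`, `candidates` (surviving, folded, labelled), `labels`
#'   (character vector), `encoded` (7 x L x N array with `labels`/`ids`
#'   attributes).
#' @export
mirna_pipeline <- function(genome, reads, format = "auto",
                           min_len = 20L, max_len = 24L,
                           k = 12L, max_hits = 20L, max_gap = 100L,
                           window_lengths = c(100L, 150L, 200L),
                           flank = 15L, L = 200L,
                           min_paired_frac = 0.6,
                           min_duplex_fraction = 0.75,
                           fold_method = c("auto", "mfe", "nussinov"),
                           verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  rd <- if (is.data.frame(reads)) reads else load_reads(reads, format)
  rd <- filter_by_length(rd, min_len, max_len)
  say("reads: ", nrow(rd), " unique sequences after length filter")

  index <- build_index(genome, k)
  loci <- map_reads(index, rd, max_hits = max_hits)
  clusters <- cluster_loci(loci, max_gap = max_gap)
  say("mapping: ", nrow(loci), " loci in ", length(clusters), " clusters")

  candidates <- list()
  for (i in seq_along(clusters))
    candidates <- c(candidates,
                    extract_candidates(index, clusters[[i]],
                                       window_lengths = window_lengths,
                                       flank = flank, min_window = min(window_lengths),
                                       cluster_id = i))
  selected <- select_hairpin_candidates(candidates,
                                        min_paired_frac = min_paired_frac,
                                        fold_method = fold_method)
  say("candidates: ", length(candidates), " windows, ",
      length(selected), " hairpin candidates")

  labels <- character(length(selected))
  for (i in seq_along(selected)) {
    lab <- label_candidate(selected[[i]],
                           min_duplex_fraction = min_duplex_fraction)
    selected[[i]]$label <- as.character(lab)
    labels[i] <- as.character(lab)
  }
  say("labels: ", sum(labels == "miRNA"), " miRNA / ",
      sum(labels == "other"), " other")

  encoded <- if (length(selected)) encode_candidates(selected, L) else NULL
  list(reads = rd, loci = loci, clusters = clusters,
       candidates = selected, labels = labels, encoded = encoded)
}

#' Synthetic cross-validation experiment
#'
#' Generates a synthetic dataset, runs [mirna_pipeline()] on it, scores
#' recovery of the planted loci against the generator's truth table, and
#' trains/evaluates the classifier with stratified k-fold
#' cross-validation on the annotation labels.
#'
#' @param spec a `sim_spec`.
#' @param folds cross-validation folds.
#' @param config a `mircnn_config`.
#' @param seed seed for the cross-validation (the generator uses
#'   `spec$seed`).
#' @param dir working directory for the generated files (default a fresh
#'   temporary directory).
#' @param run_cv set FALSE to skip classifier training (recovery only).
#' @param verbose print stage summaries.
#' @return a list: `pipeline` (see [mirna_pipeline()]), `recovery`
#'   (fractions `mirna_recovered`, `mirna_labeled`, `sirna_mislabeled`),
#'   `cv` (a `mircnn_cv`, or NULL), `truth`.
#' @export
mirna_cv_experiment <- function(spec, folds = 5L, config = mircnn_config(),
                                seed = 1L, dir = tempfile("simdata"),
                                run_cv = TRUE, verbose = TRUE) {
  ds <- generate_dataset(spec, dir = dir)
  pipe <- mirna_pipeline(ds$genome, ds$paths$reads, format = "fastq",
                         L = config$L, verbose = verbose)
  rec <- score_recovery(pipe$candidates, ds$truth)
  cv <- NULL
  if (run_cv) {
    y <- attr(pipe$encoded, "labels")
    cv <- mircnn_cv(pipe$encoded, y, folds = folds, config = config,
                    seed = seed)
  }
  list(pipeline = pipe, recovery = rec, cv = cv, truth = ds$truth)
}

#' Score candidate recovery against a generator truth table
#'
#' A planted miRNA locus counts as recovered when a surviving candidate
#' on the same chromosome and strand overlaps its mature span, and as
#' correctly labelled when such a candidate is labelled miRNA. A planted
#' siRNA locus is mislabelled when any candidate overlapping its span
#' (either strand) is labelled miRNA.
#'
#' @param candidates labelled candidates from [mirna_pipeline()].
#' @param truth the truth data.frame from [generate_dataset()].
#' @return list with fractions `mirna_recovered`, `mirna_labeled`,
#'   `sirna_mislabeled` and the underlying counts.
#' @export
score_recovery <- function(candidates, truth) {
  cand <- data.frame(
    chrom = vapply(candidates, `[[`, "", "chrom"),
    start = vapply(candidates, `[[`, 0L, "start"),
    end = vapply(candidates, `[[`, 0L, "end"),
    strand = vapply(candidates, `[[`, "", "strand"),
    label = vapply(candidates, `[[`, "", "label"),
    stringsAsFactors = FALSE)

  mir <- truth[truth$class == "miRNA", , drop = FALSE]
  sir <- truth[truth$class == "siRNA", , drop = FALSE]

  recovered <- logical(nrow(mir)); labeled <- logical(nrow(mir))
  for (i in seq_len(nrow(mir))) {
    hit <- cand$chrom == mir$chrom[i] & cand$strand == mir$strand[i] &
      cand$start < mir$mature_end[i] & cand$end > mir$mature_start[i]
    recovered[i] <- any(hit)
    labeled[i] <- any(hit & cand$label == "miRNA")
  }
  mislabeled <- logical(nrow(sir))
  for (i in seq_len(nrow(sir))) {
    hit <- cand$chrom == sir$chrom[i] &
      cand$start < sir$end[i] & cand$end > sir$start[i]
    mislabeled[i] <- any(hit & cand$label == "miRNA")
  }
  list(mirna_recovered = mean(recovered),
       mirna_labeled = mean(labeled),
       sirna_mislabeled = if (nrow(sir)) mean(mislabeled) else NA_real_,
       n_mirna = nrow(mir), n_sirna = nrow(sir),
       n_recovered = sum(recovered), n_labeled = sum(labeled),
       n_mislabeled = sum(mislabeled))
}
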