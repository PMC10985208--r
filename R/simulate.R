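RNA_BASES <- c("A", "C", "G", "U")

rand_bases <- function(n, alphabet = RNA_BASES)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

comp_rna <- function(base) c(A = "U", U = "A", C = "G", G = "C")[base]

# a base that can pair with `base` under neither Watson-Crick nor wobble
nonpairing_base <- function(base) {
  pool <- switch(base, A = c("A", "C", "G"), U = c("C", "U"),
                 G = c("A", "G"), C = c("A", "C", "U"))
  sample(pool, 1)
}

revcomp_rna <- function(seq) {
  paste(rev(c(A = "U", U = "A", C = "G", G = "C")[strsplit(seq, "")[[1]]]),
        collapse = "")
}

#' Specification of a synthetic small RNA study
#'
#' Describes a toy genome carrying planted miRNA loci (hairpin precursors
#' with a near-complementary miRNA/miRNA* duplex and two sharp read
#' stacks with homogeneous 5' ends) and siRNA-like negative loci
#' (foldable inverted repeats covered by dispersed, phase-jittered read
#' stacks on both arms). The default class ratio is 1:3
#' (miRNA:siRNA-like), matching the imbalance the classifier is trained
#' under, and identical specs produce byte-identical outputs.
#'
#' @param n_mirna_loci,n_sirna_loci number of planted loci per class.
#' @param mature_len_range mature read length range (nt).
#' @param duplex_mismatch_range total mismatched duplex positions per
#'   miRNA locus (sampled uniformly).
#' @param asym_bulge_range mature-side nucleotides in asymmetric bulges
#'   (bounded by the sampled mismatch count and by 3).
#' @param loop_len_range terminal loop length (nt); loop bases are drawn
#'   from \{A, C\} so the loop cannot self-pair.
#' @param precursor_len_range planted precursor length (nt).
#' @param mirna_read_precision fraction of miRNA-locus read mass with
#'   exact duplex 5' ends; the remainder is emitted as +/-1 nt variants.
#' @param sirna_phase_jitter s.d. (nt) of siRNA read starts around a
#'   21-nt phasing grid; 0 degenerates towards miRNA-like stacks (a
#'   warning is issued).
#' @param depth_range mature-read count range per miRNA locus; siRNA
#'   per-read counts are drawn from 5--30.
#' @param spacer_len_range inter-locus genomic spacer length (nt).
#' @param seed integer seed; all generator randomness flows from it.
#' @return an object of class `sim_spec`.
#' @export
simulation_spec <- function(n_mirna_loci = 20L, n_sirna_loci = 60L,
                            mature_len_range = c(20L, 24L),
                            duplex_mismatch_range = c(0L, 5L),
                            asym_bulge_range = c(0L, 3L),
                            loop_len_range = c(4L, 15L),
                            precursor_len_range = c(100L, 200L),
                            mirna_read_precision = 0.9,
                            sirna_phase_jitter = 3,
                            depth_range = c(30L, 150L),
                            spacer_len_range = c(150L, 250L),
                            seed = 1L) {
  stopifnot(n_mirna_loci >= 0, n_sirna_loci >= 0,
            mature_len_range[1] >= 20, mature_len_range[2] <= 24,
            duplex_mismatch_range[1] >= 0, duplex_mismatch_range[2] <= 5,
            asym_bulge_range[1] >= 0, asym_bulge_range[2] <= 3,
            loop_len_range[1] >= 4, loop_len_range[2] <= 15,
            precursor_len_range[1] >= 100, precursor_len_range[2] <= 200,
            mirna_read_precision >= 0, mirna_read_precision <= 1,
            depth_range[1] >= 1, spacer_len_range[1] >= 120)
  if (sirna_phase_jitter == 0)
    warning("sirna_phase_jitter = 0: siRNA read stacks degenerate ",
            "towards miRNA-like homogeneous 5' ends")
  structure(list(n_mirna_loci = as.integer(n_mirna_loci),
                 n_sirna_loci = as.integer(n_sirna_loci),
                 mature_len_range = as.integer(mature_len_range),
                 duplex_mismatch_range = as.integer(duplex_mismatch_range),
                 asym_bulge_range = as.integer(asym_bulge_range),
                 loop_len_range = as.integer(loop_len_range),
                 precursor_len_range = as.integer(precursor_len_range),
                 mirna_read_precision = mirna_read_precision,
                 sirna_phase_jitter = sirna_phase_jitter,
                 depth_range = as.integer(depth_range),
                 spacer_len_range = as.integer(spacer_len_range),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("sim_spec:", x$n_mirna_loci, "miRNA +", x$n_sirna_loci,
      "siRNA-like loci, seed", x$seed, "\n")
  invisible(x)
}

# scattered interior single mismatches (pairwise distance >= min_gap so
# each intervening helix segment stays long enough to be stable, away
# from the bulge run) inside positions lo..hi of an arm; infeasible
# counts are reduced until placement succeeds
pick_mismatch_positions <- function(n, lo, hi, forbidden = integer(0),
                                    min_gap = 4L) {
  avail <- setdiff(lo:hi, forbidden)
  while (n > 0) {
    for (try in 1:200) {
      pos <- sort(sample(avail, n))
      if (n == 1 || min(diff(pos)) >= min_gap) return(pos)
    }
    n <- n - 1L
  }
  integer(0)
}

#' Generate one planted miRNA locus
#'
#' Builds a mature sequence, its star as the reverse complement with the
#' sampled number of mismatches (isolated symmetric non-pairing
#' substitutions) and asymmetric-bulge nucleotides (a contiguous
#' mature-side run with no opposite partner), an \{A,C\} terminal loop,
#' and random flanks (>= 15 nt) to a precursor-range length. The mature
#' arm is chosen at random. Read stacks place a high-count mature read
#' and a lower-count star read at the 2-nt-overhang star span, plus an
#' occasional +/-1 nt 5' variant according to `mirna_read_precision`.
#' Consumes the current RNG stream.
#'
#' @param spec a `sim_spec`.
#' @return a list: `sequence` (RNA), `mature_span`, `star_span` (1-based),
#'   `reads` (data.frame offset/length/count), `class = "miRNA"`, and the
#'   designed `n_mismatch`/`n_asym_bulge_nt`.
#' @export
generate_mirna_locus <- function(spec) {
  ml <- sample(spec$mature_len_range[1]:spec$mature_len_range[2], 1)
  m_total <- sample(spec$duplex_mismatch_range[1]:spec$duplex_mismatch_range[2], 1)
  b_hi <- min(spec$asym_bulge_range[2], m_total)
  b_lo <- min(spec$asym_bulge_range[1], b_hi)
  b <- if (b_hi <= b_lo) b_lo else sample(b_lo:b_hi, 1)
  msym <- m_total - b
  lo <- 4L; hi <- ml - 3L
  if (hi - lo + 1L < msym + b + 2L)
    stop("infeasible spec: mismatches and bulges exceed the mature stem")
  bulge <- integer(0)
  if (b > 0) {
    bs <- sample(lo:(hi - b + 1L), 1)
    bulge <- bs:(bs + b - 1L)
  }
  forb <- if (length(bulge)) (min(bulge) - 3L):(max(bulge) + 3L) else integer(0)
  sym <- pick_mismatch_positions(msym, lo, hi, forb)
  msym <- length(sym)
  m_total <- msym + b

  mature <- strsplit(rand_bases(ml), "")[[1]]
  # G/C clamps at the duplex ends and around every designed defect keep
  # the MFE structure on the designed register
  gc <- function(k) sample(c("G", "C"), k, replace = TRUE)
  mature[c(1:3, (ml - 2):ml)] <- gc(6)
  for (p in sym) mature[c(p - 1L, p + 1L)] <- gc(2)
  if (length(bulge))
    mature[c(min(bulge) - 1L, max(bulge) + 1L)] <- gc(2)
  star <- character(0)
  partner_in_star <- integer(ml)
  for (i in ml:1) {
    if (i %in% bulge) next
    pos <- length(star) + 1L
    if (i %in% sym) star[pos] <- nonpairing_base(mature[i])
    else { star[pos] <- unname(comp_rna(mature[i])); partner_in_star[i] <- pos }
  }
  sl <- length(star)
  lp <- sample(spec$loop_len_range[1]:spec$loop_len_range[2], 1)
  loop <- rand_bases(lp, c("A", "C"))

  D <- ml + lp + sl
  t_lo <- max(spec$precursor_len_range[1], D + 30L)
  total <- sample(t_lo:max(t_lo, spec$precursor_len_range[2]), 1)
  f5 <- sample(15L:(total - D - 15L), 1)
  f3 <- total - D - f5

  arm5p <- sample(c(TRUE, FALSE), 1)
  mature_str <- paste(mature, collapse = "")
  star_str <- paste(star, collapse = "")
  if (arm5p) {
    seq <- paste0(rand_bases(f5), mature_str, loop, star_str, rand_bases(f3))
    m_off <- f5; s0 <- f5 + ml + lp + 1L
  } else {
    seq <- paste0(rand_bases(f5), star_str, loop, mature_str, rand_bases(f3))
    m_off <- f5 + sl + lp; s0 <- f5 + 1L
  }
  mature_span <- c(m_off + 1L, m_off + ml)
  pt <- rep(-1L, total)
  for (i in which(partner_in_star > 0)) {
    p <- s0 - 1L + partner_in_star[i]
    pt[m_off + i] <- p
    pt[p] <- m_off + i
  }
  db <- rep(".", total)
  db[pt > seq_len(total)] <- "("
  db[pt > 0 & pt < seq_len(total)] <- ")"
  designed_fold <- structure(
    list(sequence = NULL, dotbracket = paste(db, collapse = ""),
         pair_table = pt, pair_count = sum(pt > 0) %/% 2L),
    class = "fold_result")
  partners <- s0 - 1L + partner_in_star[partner_in_star > 0]
  star_span <- c(min(partners) + 2L, max(partners) + 2L)
  star_span <- pmin(pmax(star_span, 1L), total)
  star_len <- max(star_span[2] - star_span[1] + 1L, 20L)   # length filter floor
  star_span[2] <- min(star_span[1] + star_len - 1L, total)

  c_m <- sample(spec$depth_range[1]:spec$depth_range[2], 1)
  c_s <- max(1L, as.integer(round(c_m * runif(1, 0.15, 0.35))))
  reads <- data.frame(offset = c(mature_span[1] - 1L, star_span[1] - 1L),
                      length = c(ml, star_span[2] - star_span[1] + 1L),
                      count = c(c_m, c_s))
  if (runif(1) > spec$mirna_read_precision) {
    sh <- sample(c(-1L, 1L), 1)
    off <- mature_span[1] - 1L + sh
    if (off >= 0 && off + ml <= total)
      reads <- rbind(reads, data.frame(offset = off, length = ml,
                                       count = max(1L, round(0.1 * c_m))))
  }
  designed_fold$sequence <- seq
  list(sequence = seq, mature_span = mature_span, star_span = star_span,
       reads = reads, class = "miRNA",
       n_mismatch = m_total, n_asym_bulge_nt = b,
       designed_fold = designed_fold)
}

#' Generate one siRNA-like negative locus
#'
#' A long inverted repeat (arms 40--70 nt, \{A,C\} loop, >= 15 nt
#' flanks) whose reads are dispersed over both arms on a 21-nt phasing
#' grid with Gaussian 5'-end jitter and comparable counts, so the window
#' folds into a hairpin but no single duplex accounts for the read mass.
#' Consumes the current RNG stream.
#'
#' @param spec a `sim_spec`.
#' @return a list like [generate_mirna_locus()] with `class = "siRNA"`
#'   and `mature_span = NULL`.
#' @export
generate_sirna_locus <- function(spec) {
  a <- sample(40:70, 1)
  arm1 <- strsplit(rand_bases(a), "")[[1]]
  # mismatches on a ~17-nt grid so every 20-nt window of an arm contains
  # at least one: no read is a perfect reverse complement of the other
  # arm, hence none maps to a phantom opposite-strand locus
  sym <- seq(10L, a - 5L, by = 17L)
  sym <- sym + sample(-2:2, length(sym), replace = TRUE)
  sym <- sym[sym >= 4L & sym <= a - 3L]
  arm2 <- character(a)
  for (i in a:1) {
    pos <- a - i + 1L
    arm2[pos] <- if (i %in% sym) nonpairing_base(arm1[i]) else
      unname(comp_rna(arm1[i]))
  }
  lp <- sample(4:10, 1)
  loop <- rand_bases(lp, c("A", "C"))
  D <- 2L * a + lp
  t_lo <- max(spec$precursor_len_range[1], D + 30L)
  total <- sample(t_lo:max(t_lo, spec$precursor_len_range[2]), 1)
  f5 <- sample(15L:(total - D - 15L), 1)
  f3 <- total - D - f5
  seq <- paste0(rand_bases(f5), paste(arm1, collapse = ""), loop,
                paste(arm2, collapse = ""), rand_bases(f3))
  arms <- list(c(f5 + 1L, f5 + a), c(f5 + a + lp + 1L, f5 + 2L * a + lp))

  reads <- NULL
  for (arm in arms) {
    phases <- seq(arm[1], arm[2] - 20L, by = 21L)
    for (ph in phases) {
      len <- sample(20:24, 1)
      off <- ph - 1L + as.integer(round(rnorm(1, 0, spec$sirna_phase_jitter)))
      off <- min(max(off, arm[1] - 1L), arm[2] - len)
      if (off < 0) next
      reads <- rbind(reads, data.frame(offset = off, length = len,
                                       count = sample(5:30, 1)))
    }
  }
  # extra dispersed reads so no stack dominates
  extra <- sample(4:8, 1)
  for (j in seq_len(extra)) {
    arm <- arms[[1 + (j %% 2)]]
    len <- sample(20:24, 1)
    off <- sample((arm[1] - 1L):(arm[2] - len), 1)
    reads <- rbind(reads, data.frame(offset = off, length = len,
                                     count = sample(5:30, 1)))
  }
  reads <- reads[order(reads$offset, reads$length), , drop = FALSE]
  rownames(reads) <- NULL
  list(sequence = seq, mature_span = NULL, star_span = NULL,
       reads = reads, class = "siRNA")
}

#' Generate a complete synthetic dataset
#'
#' Plants `n_mirna_loci` miRNA and `n_sirna_loci` siRNA-like loci on
#' randomly chosen strands, separated by random spacers, across
#' chromosomes of at most 50 loci each. Reads are realised as duplicate
#' FASTQ records (one record per count); the truth table records each
#' locus span, class, strand and (for miRNA) the genomic mature span.
#' Output is fully deterministic given `spec$seed`.
#'
#' @param spec a `sim_spec`.
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `reads.fq` and `truth.bed` (BED6 plus mature start/end columns).
#' @return a list: `genome` ([Biostrings::DNAStringSet]), `truth`
#'   (data.frame), `loci` (generator outputs), `reads` (collapsed
#'   data.frame of unique read sequences with counts), and `paths` when
#'   `dir` was given.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  with_local_seed(spec$seed, {
    n_total <- spec$n_mirna_loci + spec$n_sirna_loci
    classes <- c(rep("miRNA", spec$n_mirna_loci),
                 rep("siRNA", spec$n_sirna_loci))
    per_chrom <- 50L
    n_chrom <- max(1L, ceiling(n_total / per_chrom))

    chrom_parts <- rep(list(character(0)), n_chrom)
    chrom_pos <- integer(n_chrom)
    truth <- NULL
    loci <- vector("list", n_total)
    read_seq <- character(0); read_count <- integer(0); read_locus <- integer(0)

    for (i in seq_len(n_total)) {
      locus <- if (classes[i] == "miRNA") generate_mirna_locus(spec)
      else generate_sirna_locus(spec)
      loci[[i]] <- locus
      strand <- sample(c("+", "-"), 1)
      len <- nchar(locus$sequence)
      ci <- 1L + (i - 1L) %/% per_chrom

      spacer <- rand_bases(sample(spec$spacer_len_range[1]:
                                    spec$spacer_len_range[2], 1),
                           c("A", "C", "G", "T"))
      dna <- chartr("U", "T", locus$sequence)
      if (strand == "-")
        dna <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(dna)))
      chrom_parts[[ci]] <- c(chrom_parts[[ci]], spacer, dna)
      start0 <- chrom_pos[ci] + nchar(spacer)
      chrom_pos[ci] <- start0 + len

      m <- locus$mature_span
      if (is.null(m)) {
        gm <- c(NA_integer_, NA_integer_)
      } else if (strand == "+") {
        gm <- c(start0 + m[1] - 1L, start0 + m[2])
      } else {
        gm <- c(start0 + len - m[2], start0 + len - m[1] + 1L)
      }
      truth <- rbind(truth, data.frame(
        chrom = sprintf("chr%d", ci), start = start0, end = start0 + len,
        name = sprintf("locus%04d", i), score = 0L, strand = strand,
        class = classes[i], mature_start = gm[1], mature_end = gm[2],
        stringsAsFactors = FALSE))

      rs <- locus$reads
      sq <- substring(chartr("U", "T", locus$sequence),
                      rs$offset + 1L, rs$offset + rs$length)
      read_seq <- c(read_seq, sq)
      read_count <- c(read_count, rs$count)
      read_locus <- c(read_locus, rep(i, nrow(rs)))
    }

    genome <- Biostrings::DNAStringSet(
      vapply(chrom_parts, paste, "", collapse = ""))
    names(genome) <- sprintf("chr%d", seq_len(n_chrom))

    agg <- rowsum(read_count, group = read_seq)
    reads <- data.frame(seq = rownames(agg), count = as.integer(agg[, 1]),
                        stringsAsFactors = FALSE)
    reads <- reads[order(-reads$count, reads$seq), , drop = FALSE]
    rownames(reads) <- NULL

    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(genome = file.path(dir, "genome.fa"),
                    reads = file.path(dir, "reads.fq"),
                    truth = file.path(dir, "truth.bed"))
      Biostrings::writeXStringSet(genome, paths$genome)
      nrec <- rep(seq_along(read_seq), read_count)
      ids <- sprintf("@l%dr%d", read_locus[nrec],
                     sequence(read_count))
      sq <- read_seq[nrec]
      writeLines(paste0(ids, "\n", sq, "\n+\n", strrep("I", nchar(sq))),
                 paths$reads)
      write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
    list(genome = genome, truth = truth, loci = loci, reads = reads,
         classes = classes, paths = paths)
  })
}
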