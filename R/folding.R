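#' Predict a secondary structure by base-pair maximisation
#'
#' Folds an RNA sequence with the Nussinov dynamic program: among all
#' nested (pseudoknot-free) structures over the pair set
#' \{AU, UA, GC, CG, GU, UG\} whose hairpin loops span more than
#' `min_loop` unpaired positions, it returns one with the maximum number
#' of base pairs. Traceback is deterministic: at each position the
#' algorithm prefers leaving the 5'-most base unpaired, and otherwise
#' pairs it with the smallest feasible partner. The folder is intentionally
#' energy-free so that an exhaustive enumeration oracle can verify it; an
#' MFE folder can be substituted anywhere a `fold_result` is consumed by
#' supplying the same fields.
#'
#' @param sequence RNA string over \{A,C,G,U\} (case-insensitive; T is
#'   accepted and read as U).
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (pairs (i, j) require j - i > min_loop). Honoured by the Nussinov
#'   method; the MFE folder uses the same minimum (3) built into its
#'   energy model.
#' @param method `"nussinov"` (the built-in base-pair maximiser) or
#'   `"mfe"` (minimum free energy via the external `RNAfold` program,
#'   which must be on the PATH).
#' @return an object of class `fold_result`: `sequence`, `dotbracket`,
#'   `pair_table` (1-based partner index, -1 if unpaired) and
#'   `pair_count`.
#' @examples
#' fold("GGGAAACCC")$dotbracket   # "(((...)))"
#' @export
fold <- function(sequence, min_loop = 3L,
                 method = c("nussinov", "mfe")) {
  method <- match.arg(method)
  fold_batch(sequence, min_loop = min_loop, method = method)[[1]]
}

#' Fold many sequences at once
#'
#' Vectorised version of [fold()]. With `method = "mfe"` all sequences
#' go through a single `RNAfold` invocation, which is much faster than
#' folding one by one.
#'
#' @param sequences character vector of RNA sequences.
#' @param min_loop,method see [fold()].
#' @return a list of `fold_result`, one per sequence.
#' @export
fold_batch <- function(sequences, min_loop = 3L,
                       method = c("nussinov", "mfe")) {
  method <- match.arg(method)
  if (length(sequences) == 0) return(list())
  if (any(!nzchar(sequences)))
    stop("sequence must be a single non-empty string")
  seqs <- toupper(chartr("Tt", "Uu", sequences))
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad))
    stop("invalid character in sequence: only A,C,G,U (or T) allowed")

  mk <- function(seq, pt, pc) {
    db <- rep(".", length(pt))
    db[pt > seq_along(pt)] <- "("
    db[pt > 0 & pt < seq_along(pt)] <- ")"
    structure(list(sequence = seq, dotbracket = paste(db, collapse = ""),
                   pair_table = pt, pair_count = pc),
              class = "fold_result")
  }

  if (method == "nussinov") {
    return(lapply(seqs, function(s) {
      res <- .nussinov_cpp(s, as.integer(min_loop))
      mk(s, res$pair_table, res$pair_count)
    }))
  }

  if (!has_rnafold())
    stop("method = 'mfe' requires the RNAfold program on the PATH")
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fa)
  out <- system2("RNAfold", c("--noPS"), stdin = fa, stdout = TRUE)
  db_lines <- out[seq(3, length(out), by = 3)]
  db <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", db_lines)
  if (length(db) != length(seqs) || any(nchar(db) != nchar(seqs)))
    stop("unexpected RNAfold output")
  lapply(seq_along(seqs), function(i) {
    pt <- .db_pairtable_cpp(db[i])
    mk(seqs[i], pt, sum(pt > 0) %/% 2L)
  })
}

#' Is the external RNAfold folder available?
#'
#' @return TRUE when the `RNAfold` executable is on the PATH.
#' @export
has_rnafold <- function() nzchar(Sys.which("RNAfold"))

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, " (", x$pair_count, " pairs)\n",
      sep = "")
  invisible(x)
}

#' Decide whether a folded window is a single-stem hairpin for a mature span
#'
#' A window counts as a hairpin for the given mature span when
#' (a) the arm system containing the mature span encloses exactly one
#' terminal loop (no multiloop separates the mature from its partner
#' region), (b) at least `min_paired_frac` of the mature-span bases are
#' paired, and (c) every mature-span partner lies on the opposite arm,
#' i.e. outside the mature span and all on one side of it.
#'
#' @param fold a `fold_result`.
#' @param mature_span integer c(start, end), 1-based inclusive, within the
#'   sequence.
#' @param min_paired_frac minimum fraction of mature bases paired
#'   (default 0.6).
#' @return a list with `hairpin` (logical) and `report` carrying each
#'   sub-check (`single_loop`, `paired_frac`, `partners_one_side`,
#'   `n_paired`).
#' @export
is_hairpin <- function(fold, mature_span, min_paired_frac = 0.6) {
  n <- nchar(fold$sequence)
  m1 <- mature_span[1]; m2 <- mature_span[2]
  stopifnot(m1 >= 1, m2 <= n, m1 <= m2)
  pt <- fold$pair_table
  idx <- m1:m2
  partners <- pt[idx]
  paired <- partners > 0
  n_paired <- sum(paired)
  paired_frac <- n_paired / length(idx)

  partners_one_side <- FALSE
  single_loop <- FALSE
  if (n_paired > 0) {
    p <- partners[paired]
    partners_one_side <- all(p > m2) || all(p < m1)
    lo <- min(c(idx, p)); hi <- max(c(idx, p))
    db <- substr(fold$dotbracket, lo, hi)
    n_loops <- length(gregexpr("\\(\\.*\\)", db)[[1]])
    if (!grepl("\\(\\.*\\)", db)) n_loops <- 0L
    single_loop <- n_loops == 1L
  }

  hairpin <- single_loop && paired_frac >= min_paired_frac &&
    partners_one_side
  list(hairpin = hairpin,
       report = list(single_loop = single_loop,
                     paired_frac = paired_frac,
                     partners_one_side = partners_one_side,
                     n_paired = n_paired))
}

#' Write a fold in Vienna format (sequence line + dot-bracket line)
#'
#' @param fold a `fold_result`.
#' @param path output path.
#' @param id header written as `>id`.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(fold, path, id = "seq1") {
  writeLines(c(paste0(">", id), fold$sequence, fold$dotbracket), path)
  invisible(path)
}
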