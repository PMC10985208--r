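#' Normalised read-coverage track for a precursor window
#'
#' Each read contributes `count / max(count)` over the positions it
#' covers; where reads overlap, the per-position maximum of the
#' normalised values is kept. Positions covered by no read are 0, so the
#' track lies in the unit interval and attains 1 wherever the most
#' abundant read
#' maps. The track is invariant to rescaling all counts.
#'
#' @param mapped_reads data.frame with columns `offset` (0-based),
#'   `length`, `count`.
#' @param n window length.
#' @return numeric vector of length `n` with values in 0..1.
#' @export
normalize_read_track <- function(mapped_reads, n) {
  track <- numeric(n)
  if (is.null(mapped_reads) || nrow(mapped_reads) == 0) return(track)
  mx <- max(mapped_reads$count)
  for (i in seq_len(nrow(mapped_reads))) {
    a <- mapped_reads$offset[i] + 1L
    b <- mapped_reads$offset[i] + mapped_reads$length[i]
    a <- max(1L, a); b <- min(n, b)
    if (a > b) next
    v <- mapped_reads$count[i] / mx
    track[a:b] <- pmax(track[a:b], v)
  }
  track
}

#' Encode a precursor candidate as a 7 x L matrix
#'
#' The distributed representation fed to the classifier: rows 1--4 are
#' the one-hot code of the nucleotide (A, U, C, G), rows 5--6 the pairing
#' state ((1,0) paired, (0,1) unpaired, (0.5,0.5) for gap/padding
#' columns), and row 7 the normalised read coverage. Columns beyond the
#' precursor length are padding: all-zero one-hot, (0.5,0.5) structure
#' code, zero coverage.
#'
#' @param candidate a folded `precursor_candidate`.
#' @param L matrix width; candidates longer than `L` are rejected (choose
#'   a shorter extraction window instead).
#' @return a 7 x L numeric matrix of class `encoded_matrix` with row
#'   names A, U, C, G, paired, unpaired, coverage, and attributes `label`
#'   (1 miRNA, 0 other, NA unlabeled) and `id`.
#' @export
encode_precursor <- function(candidate, L = 200L) {
  if (is.null(candidate$fold))
    stop("candidate must be folded before encoding")
  n <- nchar(candidate$sequence)
  if (n > L)
    stop("candidate length ", n, " exceeds L = ", L,
         "; select a shorter extraction window")
  M <- matrix(0, nrow = 7L, ncol = L,
              dimnames = list(c("A", "U", "C", "G", "paired", "unpaired",
                                "coverage"), NULL))
  bases <- strsplit(candidate$sequence, "")[[1]]
  row_of <- c(A = 1L, U = 2L, C = 3L, G = 4L)
  M[cbind(row_of[bases], seq_len(n))] <- 1
  paired <- candidate$fold$pair_table[seq_len(n)] > 0
  M[5L, seq_len(n)] <- as.numeric(paired)
  M[6L, seq_len(n)] <- as.numeric(!paired)
  if (n < L) { M[5L, (n + 1L):L] <- 0.5; M[6L, (n + 1L):L] <- 0.5 }
  M[7L, seq_len(n)] <- normalize_read_track(candidate$mapped_reads, n)
  label <- switch(candidate$label, miRNA = 1L, other = 0L, NA_integer_)
  structure(M, class = c("encoded_matrix", "matrix"), label = label,
            id = paste0(candidate$chrom, ":", candidate$start, "-",
                        candidate$end, "(", candidate$strand, ")"))
}

#' Recover sequence and pairing states from an encoded matrix
#'
#' Inverse of rows 1--6 of [encode_precursor()]; used to verify the
#' encoding round-trip.
#'
#' @param m an `encoded_matrix`.
#' @return list with `sequence` (RNA string) and `paired` (logical
#'   vector), both restricted to the non-padding columns.
#' @export
decode_precursor <- function(m) {
  occupied <- colSums(m[1:4, , drop = FALSE]) > 0
  n <- sum(occupied)
  bases <- c("A", "U", "C", "G")[apply(m[1:4, seq_len(n), drop = FALSE],
                                       2, which.max)]
  list(sequence = paste(bases, collapse = ""),
       paired = m[5L, seq_len(n)] == 1)
}

#' Encode a set of candidates as a batch array
#'
#' @param candidates list of folded, labelled `precursor_candidate`.
#' @param L matrix width.
#' @return numeric array of dim (7, L, N) with attributes `labels`
#'   (integer vector, 1 miRNA / 0 other / NA) and `ids`.
#' @export
encode_candidates <- function(candidates, L = 200L) {
  mats <- lapply(candidates, encode_precursor, L = L)
  arr <- array(0, dim = c(7L, L, length(mats)))
  for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
  attr(arr, "labels") <- vapply(mats, function(m) attr(m, "label") %||%
                                  NA_integer_, 1L)
  attr(arr, "ids") <- vapply(mats, attr, "", "id")
  arr
}
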