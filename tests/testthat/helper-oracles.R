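# Independent brute-force oracles used across the test files.

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# Maximum number of nested base pairs by exhaustive enumeration of all
# valid structures (exponential; for short sequences only). Independent
# of the dynamic-programming recursion: position i is either unpaired or
# paired with every allowed j, recursing on the inside/outside split.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (oracle_can_pair(s[i], s[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) +
                      if (k < j) rec(k + 1L, j) else 0L)
    }
    best
  }
  if (length(s) < 2) return(0L)
  rec(1L, length(s))
}

# Naive quadruple-loop convolution (valid, stride 1) with optional ReLU.
oracle_conv <- function(input, kernels, bias, relu = TRUE) {
  di <- dim(input); dk <- dim(kernels)
  C <- di[1]; H <- di[2]; W <- di[3]
  K <- dk[1]; kh <- dk[3]; kw <- dk[4]
  out <- array(0, c(K, H - kh + 1, W - kw + 1))
  for (k in 1:K) for (i in 1:(H - kh + 1)) for (j in 1:(W - kw + 1)) {
    s <- bias[k]
    for (c in 1:C) for (x in 1:kh) for (y in 1:kw)
      s <- s + kernels[k, c, x, y] * input[c, i + x - 1, j + y - 1]
    out[k, i, j] <- if (relu) max(0, s) else s
  }
  out
}

oracle_maxpool <- function(input, ph = 2L, pw = 2L) {
  di <- dim(input)
  C <- di[1]; Ho <- di[2] %/% ph; Wo <- di[3] %/% pw
  out <- array(0, c(C, Ho, Wo))
  for (c in 1:C) for (i in 1:Ho) for (j in 1:Wo)
    out[c, i, j] <- max(input[c, ((i - 1) * ph + 1):(i * ph),
                               ((j - 1) * pw + 1):(j * pw)])
  out
}

# Exact full-scan string search on both strands, 0-based half-open.
oracle_map <- function(chroms, read) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  out <- NULL
  w <- nchar(read)
  for (nm in names(chroms)) {
    g <- chroms[[nm]]
    for (p in seq_len(nchar(g) - w + 1L)) {
      seg <- substr(g, p, p + w - 1L)
      if (seg == read)
        out <- rbind(out, data.frame(chrom = nm, start = p - 1L,
                                     end = p - 1L + w, strand = "+"))
      if (seg == rc(read))
        out <- rbind(out, data.frame(chrom = nm, start = p - 1L,
                                     end = p - 1L + w, strand = "-"))
    }
  }
  out
}

# Identity count of the best ungapped overlap, position-by-position scan.
oracle_identity <- function(query, ref) {
  q <- strsplit(chartr("U", "T", toupper(query)), "")[[1]]
  r <- strsplit(chartr("U", "T", toupper(ref)), "")[[1]]
  best <- 0L
  for (off in (-(length(q) - 1L)):(length(r) - 1L)) {
    n <- 0L
    for (i in seq_along(q)) {
      j <- i + off
      if (j >= 1 && j <= length(r) && q[i] == r[j]) n <- n + 1L
    }
    best <- max(best, n)
  }
  best
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# A perfect inverted-repeat hairpin: stem of `stem` pairs (random),
# {A,C} loop of `loop` nt, optional random flanks.
make_perfect_hairpin <- function(stem = 21L, loop = 4L,
                                 flank5 = 0L, flank3 = 0L) {
  arm <- random_rna(stem)
  rc <- paste(rev(c(A = "U", U = "A", C = "G",
                    G = "C")[strsplit(arm, "")[[1]]]), collapse = "")
  lp <- paste(sample(c("A", "C"), loop, replace = TRUE), collapse = "")
  list(sequence = paste0(random_rna(flank5), arm, lp, rc, random_rna(flank3)),
       mature_span = c(flank5 + 1L, flank5 + stem),
       arm = arm, stem = stem, loop = loop, flank5 = flank5)
}

# A hairpin whose fold is unambiguous under base-pair maximisation:
# {G,C} arms with {A} loop and flanks admit no A:U or G:U pairs, so the
# only pairs available are the designed stem (plus possible same-count
# register ties within the arms for repetitive arms; arms are random).
make_gc_hairpin <- function(stem = 21L, loop = 6L, flank5 = 0L,
                            flank3 = 0L) {
  arm <- paste(sample(c("G", "C"), stem, replace = TRUE), collapse = "")
  rc <- paste(rev(chartr("GC", "CG", strsplit(arm, "")[[1]])), collapse = "")
  list(sequence = paste0(strrep("A", flank5), arm, strrep("A", loop), rc,
                         strrep("A", flank3)),
       mature_span = c(flank5 + 1L, flank5 + stem),
       arm = arm, stem = stem, loop = loop, flank5 = flank5)
}

# Wrap a sequence + fold + reads into a minimal candidate object.
make_candidate <- function(sequence, mature_span, reads = NULL,
                           fold_method = "nussinov", cluster_count = NULL) {
  fl <- fold(sequence, method = fold_method)
  if (is.null(reads))
    reads <- data.frame(offset = mature_span[1] - 1L,
                        length = mature_span[2] - mature_span[1] + 1L,
                        count = 10L, read_id = "r1")
  if (is.null(reads$read_id))
    reads$read_id <- sprintf("r%d", seq_len(nrow(reads)))
  structure(list(chrom = "chr1", strand = "+", start = 0L,
                 end = nchar(sequence), sequence = sequence, fold = fl,
                 mapped_reads = reads, mature_span = mature_span,
                 label = "unlabeled", cluster_id = 1L,
                 cluster_count = cluster_count %||% sum(reads$count)),
            class = "precursor_candidate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
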