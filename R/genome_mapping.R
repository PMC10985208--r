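#' Build a genome index for exact-match read placement
#'
#' Loads the genome (FASTA path or `DNAStringSet`) and wraps it for exact
#' substring matching. Matching itself is delegated to Biostrings; the
#' "index" therefore costs no preprocessing, and [index_lookup()] resolves
#' any k-mer to exactly the positions where it occurs.
#'
#' @param genome path to a genome FASTA file, or a
#'   [Biostrings::DNAStringSet].
#' @param k the seed length recorded on the index; it fixes the k-mer size
#'   used by [index_lookup()] and [n_indexed_positions()]. Must not exceed
#'   the shortest chromosome.
#' @return an object of class `genome_index`.
#' @export
build_index <- function(genome, k = 12L) {
  seqs <- if (inherits(genome, "DNAStringSet")) genome
  else Biostrings::readDNAStringSet(genome)
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names in genome")
  if (length(seqs) == 0) stop("genome is empty")
  if (k < 1 || k > min(Biostrings::width(seqs)))
    stop("k must satisfy 1 <= k <= shortest chromosome length")
  structure(list(sequences = seqs, k = as.integer(k)),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$sequences), "sequence(s),",
      sum(Biostrings::width(x$sequences)), "bp, k =", x$k, "\n")
  invisible(x)
}

#' Number of k-mer start positions covered by the index
#'
#' @param index a `genome_index`.
#' @return `sum(len - k + 1)` over chromosomes.
#' @export
n_indexed_positions <- function(index) {
  sum(pmax(Biostrings::width(index$sequences) - index$k + 1L, 0L))
}

#' Look up every occurrence of a k-mer in the indexed genome
#'
#' @param index a `genome_index`.
#' @param kmer a DNA string of length `index$k`.
#' @return data.frame with columns `chrom` and `pos` (0-based start), one
#'   row per forward-strand occurrence.
#' @export
index_lookup <- function(index, kmer) {
  if (nchar(kmer) != index$k) stop("kmer length must equal k = ", index$k)
  hits <- lapply(seq_along(index$sequences), function(i) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(kmer),
                                  index$sequences[[i]])
    if (length(m) == 0) return(NULL)
    data.frame(chrom = names(index$sequences)[i],
               pos = BiocGenerics::start(m) - 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      stringsAsFactors = FALSE)
  out
}

#' Map a single read to the genome by exact matching
#'
#' Reports every exact, full-length occurrence of the read on either
#' strand (zero mismatches). A minus-strand locus means the read equals
#' the reverse complement of the genomic segment. Coordinates are 0-based
#' half-open.
#'
#' @param index a `genome_index`.
#' @param read a read sequence (character, DNA alphabet) or a one-row
#'   collapsed-read data.frame.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `read_id`, `count`, ordered by (chrom, start, strand). Empty when the
#'   read does not map.
#' @export
map_read <- function(index, read) {
  df <- if (is.character(read))
    data.frame(read_id = "read1", seq = toupper(read), count = 1L,
               stringsAsFactors = FALSE)
  else read
  map_reads(index, df, max_hits = Inf)
}

#' Map collapsed reads to the genome by exact matching
#'
#' Batch version of [map_read()] using Biostrings preprocessed
#' dictionaries. Reads placed at more than `max_hits` genomic sites are
#' treated as repeat-derived and discarded (with a message).
#'
#' @param index a `genome_index`.
#' @param reads a collapsed read data.frame ([load_reads()]).
#' @param max_hits multi-mapping cutoff.
#' @return data.frame of mapped loci (`chrom`, `start`, `end`, `strand`,
#'   `read_id`, `count`), 0-based half-open, ordered by
#'   (chrom, start, strand, read_id).
#' @export
map_reads <- function(index, reads, max_hits = 20L) {
  if (nrow(reads) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      read_id = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  if (any(nchar(reads$seq) < index$k))
    stop("all reads must be at least k = ", index$k, " nt long")
  chrom_names <- names(index$sequences)
  widths <- nchar(reads$seq)
  pieces <- list()
  for (w in sort(unique(widths))) {
    sel <- which(widths == w)
    fwd <- Biostrings::DNAStringSet(reads$seq[sel])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (ci in seq_along(index$sequences)) {
      subj <- index$sequences[[ci]]
      for (str in c("+", "-")) {
        m <- Biostrings::matchPDict(if (str == "+") pd_f else pd_r, subj)
        st <- Biostrings::startIndex(m)
        hit <- which(lengths(st) > 0)
        if (length(hit) == 0) next
        starts <- unlist(st[hit], use.names = FALSE) - 1L
        ridx <- rep(sel[hit], lengths(st[hit]))
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = chrom_names[ci], start = starts, end = starts + w,
          strand = str, read_id = reads$read_id[ridx],
          count = reads$count[ridx], stringsAsFactors = FALSE)
      }
    }
  }
  loci <- if (length(pieces)) do.call(rbind, pieces)
  else data.frame(chrom = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  read_id = character(0), count = integer(0),
                  stringsAsFactors = FALSE)
  if (is.finite(max_hits) && nrow(loci) > 0) {
    nh <- table(loci$read_id)
    repeats <- names(nh)[nh > max_hits]
    if (length(repeats) > 0) {
      message("discarded ", length(repeats),
              " read(s) mapping to more than ", max_hits, " sites")
      loci <- loci[!(loci$read_id %in% repeats), , drop = FALSE]
    }
  }
  loci <- loci[order(loci$chrom, loci$start, loci$strand, loci$read_id), ,
               drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Cluster mapped loci into candidate regions
#'
#' Same-chromosome, same-strand loci whose spans lie within `max_gap`
#' nucleotides of each other are merged transitively (IRanges reduce);
#' every locus belongs to exactly one cluster. The default gap of 100 nt
#' keeps a mature/star pair of one precursor (plant precursors are
#' 100--200 bp) in a single cluster.
#'
#' @param loci mapped-locus data.frame from [map_reads()].
#' @param max_gap maximum gap (nt) bridged when merging.
#' @return a list of clusters, each a list with `chrom`, `strand`,
#'   `start`, `end` (0-based half-open span) and `loci` (member rows).
#' @export
cluster_loci <- function(loci, max_gap = 100L) {
  if (nrow(loci) == 0) return(list())
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L, loci$end),
                               strand = loci$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  memb <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  lapply(seq_along(red), function(i) {
    rows <- loci[memb == i, , drop = FALSE]
    rownames(rows) <- NULL
    list(chrom = as.character(GenomicRanges::seqnames(red)[i]),
         strand = as.character(GenomicRanges::strand(red)[i]),
         start = BiocGenerics::start(red)[i] - 1L,
         end = BiocGenerics::end(red)[i],
         loci = rows)
  })
}

#' Write mapped loci or cluster spans as BED6
#'
#' @param x a mapped-locus data.frame or the cluster list from
#'   [cluster_loci()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (is.data.frame(x)) {
    bed <- data.frame(x$chrom, x$start, x$end, x$read_id, x$count, x$strand)
  } else {
    bed <- data.frame(vapply(x, `[[`, "", "chrom"),
                      vapply(x, `[[`, 0L, "start"),
                      vapply(x, `[[`, 0L, "end"),
                      sprintf("cluster%d", seq_along(x)),
                      vapply(x, function(cl) sum(cl$loci$count), 0L),
                      vapply(x, `[[`, "", "strand"))
  }
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
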