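#' Load and collapse small RNA reads
#'
#' Reads small RNA sequences from FASTQ, FASTA or count-annotated
#' ("collapsed") FASTA and collapses identical sequences into unique reads
#' with summed counts. Sequences are upper-cased and U is normalised to T
#' (the internal alphabet is DNA); reads containing N are dropped with a
#' message, because downstream mapping is exact-match only. Input is
#' assumed adapter-trimmed.
#'
#' Collapsed-FASTA headers may carry counts either as `>id_count` or as
#' `>id x count`; both dialects are accepted.
#'
#' @param path path to the read file.
#' @param format one of `"auto"`, `"fastq"`, `"fasta"`, `"collapsed-fasta"`.
#'   `"auto"` infers FASTQ from a `.fastq`/`.fq` extension and plain FASTA
#'   otherwise.
#' @return a data.frame with columns `read_id`, `seq`, `count`, one row per
#'   unique sequence, ordered by decreasing count then sequence. The number
#'   of N-containing reads dropped is attached as attribute `"n_dropped"`.
#'   An empty file yields an empty data.frame.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTACGTACGTACGTACGTA", "+", "IIIIIIIIIIIIIIIIIIIII",
#'              "@r2", "ACGTACGTACGTACGTACGTA", "+", "IIIIIIIIIIIIIIIIIIIII"),
#'            fq)
#' load_reads(fq)
#' @export
load_reads <- function(path,
                       format = c("auto", "fastq", "fasta", "collapsed-fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read file not found: ", path)
  if (file.size(path) == 0) return(empty_reads())
  if (format == "auto")
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"

  recs <- tryCatch(
    Biostrings::readBStringSet(path,
                               format = if (format == "fastq") "fastq" else "fasta"),
    error = function(e)
      stop("malformed ", format, " record in '", path, "': ",
           conditionMessage(e), call. = FALSE))
  if (length(recs) == 0) return(empty_reads())

  seqs <- chartr("u", "t", tolower(as.character(recs)))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("malformed record ", which(bad)[1], " in '", path,
         "': sequence contains characters outside A,C,G,T,U,N")

  counts <- rep(1L, length(seqs))
  if (format == "collapsed-fasta") {
    hdr <- names(recs)
    m1 <- regmatches(hdr, regexec("^(\\S+)\\s+x\\s*([0-9]+)\\s*$", hdr))
    m2 <- regmatches(hdr, regexec("^(.*)_([0-9]+)$", hdr))
    for (i in seq_along(hdr)) {
      if (length(m1[[i]]) == 3) counts[i] <- as.integer(m1[[i]][3])
      else if (length(m2[[i]]) == 3) counts[i] <- as.integer(m2[[i]][3])
      else stop("malformed collapsed-fasta header at record ", i, " in '",
                path, "': ", hdr[i])
    }
  }

  hasN <- grepl("N", seqs, fixed = TRUE)
  n_dropped <- sum(counts[hasN])
  if (n_dropped > 0)
    message("dropped ", n_dropped, " read(s) containing N")
  seqs <- seqs[!hasN]; counts <- counts[!hasN]
  if (length(seqs) == 0) return(empty_reads(n_dropped))

  agg <- rowsum(counts, group = seqs)
  out <- data.frame(seq = rownames(agg), count = as.integer(agg[, 1]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  out <- data.frame(read_id = sprintf("read%d", seq_len(nrow(out))),
                    seq = out$seq, count = out$count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

empty_reads <- function(n_dropped = 0L) {
  out <- data.frame(read_id = character(0), seq = character(0),
                    count = integer(0), stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Filter reads by the miRNA length range
#'
#' Keeps reads whose sequence length lies in `[min_len, max_len]`
#' (defaults 20--24 nt, the canonical plant miRNA length range); everything
#' outside the range is excluded. Order is preserved and the filter is
#' idempotent.
#'
#' @param reads a collapsed read data.frame as returned by [load_reads()].
#' @param min_len,max_len inclusive length bounds.
#' @return the filtered data.frame.
#' @export
filter_by_length <- function(reads, min_len = 20L, max_len = 24L) {
  stopifnot(min_len <= max_len)
  len <- nchar(reads$seq)
  out <- reads[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write collapsed reads as count-annotated FASTA
#'
#' Headers follow the `>id_count` dialect.
#'
#' @param reads a collapsed read data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0)
    writeLines(paste0(">", reads$read_id, "_", reads$count, "\n", reads$seq),
               con, sep = "\n")
  invisible(path)
}
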