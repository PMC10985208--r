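# Build a small genome with a planted locus and run mapping + clustering
# to get real clusters for extraction tests.
plant_genome <- function(locus_dna, at = 1000L, chrom_len = 10000L,
                         strand = "+") {
  set.seed(61)
  g <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
             collapse = "")
  if (strand == "-")
    locus_dna <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(locus_dna)))
  paste0(substr(g, 1, at), locus_dna,
         substr(g, at + nchar(locus_dna) + 1L, chrom_len))
}

test_that("three anchorings of the mature read are emitted per window", {
  set.seed(62)
  read <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                collapse = "")
  g <- plant_genome(read, at = 1000L)
  idx <- build_index(Biostrings::DNAStringSet(c(chr1 = g)))
  rd <- data.frame(read_id = "r1", seq = read, count = 5L,
                   stringsAsFactors = FALSE)
  cl <- cluster_loci(map_reads(idx, rd))
  cl <- Filter(function(c) c$strand == "+", cl)
  expect_length(cl, 1L)
  cands <- extract_candidates(idx, cl[[1]], window_lengths = 100L)
  expect_length(cands, 3L)
  for (cand in cands) {
    expect_equal(cand$end - cand$start, 100L)
    expect_equal(nchar(cand$sequence), 100L)
    expect_equal(nrow(cand$mapped_reads), 1L)
    m <- cand$mature_span
    expect_equal(m[2] - m[1] + 1L, 21L)
    # the window sequence contains the read at the mature span
    expect_equal(substr(cand$sequence, m[1], m[2]), chartr("T", "U", read))
  }
})

test_that("minus-strand windows are reverse-complemented with offsets flipped", {
  hp <- make_perfect_hairpin(stem = 21, loop = 6, flank5 = 30, flank3 = 30)
  dna <- chartr("U", "T", hp$sequence)
  mature_dna <- substr(dna, hp$mature_span[1], hp$mature_span[2])
  rd <- data.frame(read_id = "r1", seq = mature_dna, count = 9L,
                   stringsAsFactors = FALSE)
  g_plus <- plant_genome(dna, at = 2000L)
  g_minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g_plus)))          # whole-genome mirror
  res <- mapply(function(g, strand) {
    idx <- build_index(Biostrings::DNAStringSet(c(chr1 = g)))
    cl <- cluster_loci(map_reads(idx, rd))
    cl <- Filter(function(c) c$strand == strand, cl)
    expect_length(cl, 1L)
    extract_candidates(idx, cl[[1]], window_lengths = 100L)
  }, list(g_plus, g_minus), c("+", "-"), SIMPLIFY = FALSE)
  # strand round trip: the transcribed candidate windows are identical
  seq_p <- vapply(res[[1]], `[[`, "", "sequence")
  seq_m <- vapply(res[[2]], `[[`, "", "sequence")
  expect_setequal(seq_p, seq_m)
  sp <- vapply(res[[1]], function(x) x$mature_span, c(1L, 2L))
  sm <- vapply(res[[2]], function(x) x$mature_span, c(1L, 2L))
  expect_equal(sp[, order(seq_p)], sm[, order(seq_m)])
})

test_that("windows near a contig end are clipped or dropped", {
  set.seed(63)
  read <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                collapse = "")
  g <- paste0(substr(plant_genome(read, at = 5L, chrom_len = 3000L), 1, 3000))
  idx <- build_index(Biostrings::DNAStringSet(c(chr1 = g)))
  rd <- data.frame(read_id = "r1", seq = read, count = 2L,
                   stringsAsFactors = FALSE)
  cl <- Filter(function(c) c$strand == "+", cluster_loci(map_reads(idx, rd)))
  cands <- extract_candidates(idx, cl[[1]])
  expect_gt(length(cands), 0L)
  for (cand in cands) {
    expect_gte(cand$start, 0L)
    expect_gte(cand$end - cand$start, 100L)   # clipped windows >= 100 nt
    m <- cand$mature_span                     # mature still inside
    expect_true(m[1] >= 1 && m[2] <= nchar(cand$sequence))
  }
  # a read on a short contig with no room for any 100-nt window
  tiny <- paste0(strrep("T", 3), read, strrep("T", 3))
  idx2 <- build_index(Biostrings::DNAStringSet(c(chr1 = tiny)), k = 12L)
  cl2 <- Filter(function(c) c$strand == "+",
                cluster_loci(map_reads(idx2, rd)))
  expect_message(
    out <- extract_candidates(idx2, cl2[[1]], window_lengths = 100L),
    "no valid window")
  expect_length(out, 0L)
})

test_that("hairpin selection keeps one best candidate per cluster", {
  hp <- make_perfect_hairpin(stem = 24, loop = 6, flank5 = 40, flank3 = 40)
  dna <- chartr("U", "T", hp$sequence)
  g <- plant_genome(dna, at = 1500L)
  idx <- build_index(Biostrings::DNAStringSet(c(chr1 = g)))
  mature_dna <- substr(dna, hp$mature_span[1], hp$mature_span[2])
  rd <- data.frame(read_id = "r1", seq = mature_dna, count = 30L,
                   stringsAsFactors = FALSE)
  cl <- Filter(function(c) c$strand == "+", cluster_loci(map_reads(idx, rd)))
  cands <- extract_candidates(idx, cl[[1]])
  expect_gt(length(cands), 1L)
  kept <- select_hairpin_candidates(cands, fold_method = "nussinov")
  expect_length(kept, 1L)                      # dedup to one per cluster
  expect_true(kept[[1]]$hairpin)
  expect_s3_class(kept[[1]]$fold, "fold_result")
  # candidate invariants
  k <- kept[[1]]
  expect_equal(nchar(k$sequence), k$end - k$start)
  expect_true(all(k$mapped_reads$offset + k$mapped_reads$length <=
                    nchar(k$sequence)))

  # a structureless region yields no candidate
  set.seed(64)
  flat <- strrep("A", 3000)
  flat <- paste0(substr(flat, 1, 1000), mature_dna,
                 substr(flat, 1001 + nchar(mature_dna), 3000))
  idx2 <- build_index(Biostrings::DNAStringSet(c(chr1 = flat)))
  cl2 <- Filter(function(c) c$strand == "+",
                cluster_loci(map_reads(idx2, rd)))
  cands2 <- extract_candidates(idx2, cl2[[1]])
  expect_length(select_hairpin_candidates(cands2, fold_method = "nussinov"),
                0L)
})
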