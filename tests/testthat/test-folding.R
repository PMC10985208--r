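test_that("fold reproduces hand-checked structures", {
  f <- fold("GGGAAACCC")
  expect_equal(f$pair_count, 3L)
  expect_equal(f$dotbracket, "(((...)))")
  expect_equal(f$pair_table[1:3], c(9L, 8L, 7L))

  expect_equal(fold("AAAAAAA")$pair_count, 0L)       # no complement
  expect_equal(fold("AAAAAAA")$dotbracket, ".......")
  expect_equal(fold("GC")$pair_count, 0L)            # loop constraint
  expect_error(fold("ACGX"), "invalid character")
  expect_error(fold(""), "non-empty")
})

test_that("fold structures are well-formed", {
  set.seed(11)
  for (i in 1:30) {
    f <- fold(random_rna(sample(5:60, 1)))
    pt <- f$pair_table
    n <- nchar(f$sequence)
    expect_equal(nchar(f$dotbracket), n)
    paired <- which(pt > 0)
    # involution
    expect_true(all(pt[pt[paired]] == paired))
    # min loop and complementarity
    s <- strsplit(f$sequence, "")[[1]]
    for (i2 in paired) {
      j <- pt[i2]
      expect_true(abs(j - i2) > 3)
      expect_true(oracle_can_pair(s[i2], s[j]))
    }
    expect_equal(f$pair_count, length(paired) / 2)
  }
})

test_that("fold pair counts equal exhaustive enumeration on short RNAs", {
  set.seed(12)
  for (i in 1:60) {
    s <- random_rna(sample(5:10, 1))
    expect_equal(fold(s)$pair_count, oracle_max_pairs(s), info = s)
  }
})

test_that("pair count is monotone as the loop constraint relaxes", {
  set.seed(13)
  for (i in 1:20) {
    s <- random_rna(15)
    pc <- vapply(c(5L, 4L, 3L, 2L), function(ml) fold(s, ml)$pair_count, 0L)
    expect_true(all(diff(pc) >= 0))
  }
})

test_that("reverse complementation mirrors optima (wobble-free alphabet)", {
  # mirroring maps a structure of s onto one of revcomp(s) pair for pair
  # when only Watson-Crick pairs are possible (a G:U pair would map onto
  # the non-pairing A:C, so the symmetry holds on G/C-only strings)
  set.seed(15)
  rc <- function(x) paste(rev(c(A = "U", U = "A", C = "G",
                                G = "C")[strsplit(x, "")[[1]]]),
                          collapse = "")
  for (i in 1:20) {
    s <- paste(sample(c("G", "C"), sample(8:40, 1), replace = TRUE),
               collapse = "")
    expect_equal(fold(rc(s))$pair_count, fold(s)$pair_count, info = s)
  }
})

test_that("the MFE method produces consistent fold_result objects", {
  skip_if_not(has_rnafold())
  hp <- make_perfect_hairpin(stem = 20, loop = 6, flank5 = 10, flank3 = 10)
  f <- fold(hp$sequence, method = "mfe")
  expect_s3_class(f, "fold_result")
  expect_equal(nchar(f$dotbracket), nchar(hp$sequence))
  pt <- f$pair_table
  paired <- which(pt > 0)
  expect_true(all(pt[pt[paired]] == paired))
  # the designed stem dominates the MFE structure
  m <- hp$mature_span
  expect_gte(mean(pt[m[1]:m[2]] > 0), 0.9)
  # batch folding matches one-by-one folding
  seqs <- c(hp$sequence, make_perfect_hairpin(15, 5)$sequence)
  fb <- fold_batch(seqs, method = "mfe")
  expect_equal(fb[[1]]$dotbracket, f$dotbracket)
})

test_that("is_hairpin accepts a clean stem and rejects degenerate windows", {
  set.seed(16)
  hp <- make_gc_hairpin(stem = 28, loop = 4, flank5 = 0, flank3 = 0)
  f <- fold(hp$sequence)
  res <- is_hairpin(f, hp$mature_span)
  expect_true(res$hairpin)
  expect_equal(res$report$paired_frac, 1)

  # unpaired homopolymer
  fu <- fold(strrep("A", 60))
  expect_false(is_hairpin(fu, c(10, 30))$hairpin)

  # a mature span straddling the junction of two concatenated inverted
  # repeats: its partners split across the multiloop, one half pairing
  # upstream (stem 1), the other downstream (stem 2). Alphabet-disjoint
  # arms (G:C stem then A:U stem) make the optimum unambiguous.
  seq2 <- paste0(strrep("G", 12), "AAAA", strrep("C", 12),
                 strrep("A", 12), "CCCC", strrep("U", 12))
  f2 <- fold(seq2)
  span <- c(21L, 36L)                 # last 8 nt of stem 1 + first 8 of stem 2
  partners <- f2$pair_table[span[1]:span[2]]
  partners <- partners[partners > 0]
  expect_true(any(partners < 21) && any(partners > 36))
  r2 <- is_hairpin(f2, span)
  expect_false(r2$hairpin)
  expect_false(r2$report$partners_one_side)
})
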