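# Duplex constructions use explicit sequences so the designed pairing is
# unambiguous under base-pair maximisation.

test_that("locate_star applies the 2-nt 3' overhang to a perfect duplex", {
  set.seed(20)
  hp <- make_gc_hairpin(stem = 21, loop = 6, flank5 = 10, flank3 = 10)
  f <- fold(hp$sequence)
  m <- hp$mature_span
  st <- locate_star(f, m)
  # partners of the mature run from loop end to the 3' arm end; the star
  # read is that span shifted downstream by the overhang
  partners <- f$pair_table[m[1]:m[2]]
  expect_equal(st, c(min(partners) + 2L, max(partners) + 2L))
  expect_equal(st[2] - st[1] + 1L, 21L)

  # fully unpaired mature -> sentinel
  fu <- fold(strrep("A", 80))
  expect_length(locate_star(fu, c(20, 40)), 0L)
})

test_that("a perfect duplex yields an all-clear report for stems 19-24", {
  set.seed(25)
  for (stem in 19:24) {
    hp <- make_gc_hairpin(stem = stem, loop = 5, flank5 = 6, flank3 = 6)
    f <- fold(hp$sequence)
    st <- locate_star(f, hp$mature_span)
    rep <- evaluate_duplex(f, hp$mature_span, st)
    expect_equal(rep$n_mismatch, 0L, info = stem)
    expect_equal(rep$n_asym_bulge_nt, 0L)
    expect_false(rep$has_secondary_stem)
    expect_false(rep$has_large_loop)
    expect_true(rep$passes)
  }
})

# helper constructing a duplex with chosen mature-side defects: symmetric
# 1-nt mismatches at `sym` (mature positions) and a bulge run of length b
# at `bulge_at`. The wobble-free alphabet ({G,C} stem, A at defects and
# in the loop) pins the fold to the designed pairing exactly.
make_defect_duplex <- function(ml = 21L, sym = integer(0), bulge_at = 0L,
                               b = 0L) {
  mature <- sample(c("G", "C"), ml, replace = TRUE)
  bulge <- if (b > 0) bulge_at:(bulge_at + b - 1L) else integer(0)
  mature[c(sym, bulge)] <- "A"          # unpairable defect positions
  star <- character(0)
  for (i in ml:1) {
    if (i %in% bulge) next
    star <- c(star, if (i %in% sym) "A" else
      chartr("GC", "CG", mature[i]))
  }
  seq <- paste0(paste(mature, collapse = ""), strrep("A", 6),
                paste(star, collapse = ""))
  list(sequence = seq, mature_span = c(1L, ml))
}

test_that("mismatch and asymmetric-bulge counting matches the construction", {
  set.seed(21)
  # scattered symmetric mismatches count as mismatches, not bulges
  d <- make_defect_duplex(ml = 24L, sym = c(6L, 11L, 16L))
  f <- fold(d$sequence)
  st <- locate_star(f, d$mature_span)
  rep <- evaluate_duplex(f, d$mature_span, st)
  expect_equal(rep$n_mismatch, 3L)
  expect_equal(rep$n_asym_bulge_nt, 0L)
  expect_true(rep$passes)

  # a 4-nt mature-side bulge opposite 0 nt: 4 asymmetric nucleotides
  d4 <- make_defect_duplex(ml = 24L, bulge_at = 10L, b = 4L)
  f4 <- fold(d4$sequence)
  st4 <- locate_star(f4, d4$mature_span)
  rep4 <- evaluate_duplex(f4, d4$mature_span, st4)
  expect_equal(rep4$n_asym_bulge_nt, 4L)
  expect_false(rep4$passes)        # only three bulged nt are allowed

  # six scattered mismatches exceed the five allowed
  d6 <- make_defect_duplex(ml = 24L, sym = c(5L, 8L, 11L, 14L, 17L, 20L))
  f6 <- fold(d6$sequence)
  st6 <- locate_star(f6, d6$mature_span)
  rep6 <- evaluate_duplex(f6, d6$mature_span, st6)
  expect_gte(rep6$n_mismatch, 6L)
  expect_false(rep6$passes)
})

test_that("asymmetric bulges never exceed mismatches; counts are monotone", {
  set.seed(22)
  for (i in 1:25) {
    nsym <- sample(0:3, 1); b <- sample(0:3, 1)
    sym <- if (nsym) seq(6L, by = 4L, length.out = nsym) else integer(0)
    d <- make_defect_duplex(ml = 24L, sym = sym,
                            bulge_at = if (b) 18L else 0L, b = b)
    f <- fold(d$sequence)
    st <- locate_star(f, d$mature_span)
    rep <- evaluate_duplex(f, d$mature_span, st)
    expect_lte(rep$n_asym_bulge_nt, rep$n_mismatch)
  }
  # adding one more symmetric mismatch never decreases the count
  base <- c(6L, 11L)
  d2 <- make_defect_duplex(ml = 24L, sym = base)
  d3 <- make_defect_duplex(ml = 24L, sym = c(base, 16L))
  f2 <- fold(d2$sequence); f3 <- fold(d3$sequence)
  r2 <- evaluate_duplex(f2, d2$mature_span, locate_star(f2, d2$mature_span))
  r3 <- evaluate_duplex(f3, d3$mature_span, locate_star(f3, d3$mature_span))
  expect_gte(r3$n_mismatch, r2$n_mismatch)
})

test_that("label_candidate separates precise stacks from read smears", {
  set.seed(23)
  hp <- make_gc_hairpin(stem = 21, loop = 6, flank5 = 20, flank3 = 20)
  f <- fold(hp$sequence)
  m <- hp$mature_span
  st <- locate_star(f, m)
  precise <- data.frame(offset = c(m[1] - 1L, st[1] - 1L),
                        length = c(21L, st[2] - st[1] + 1L),
                        count = c(50L, 12L))
  cand <- make_candidate(hp$sequence, m, precise)
  expect_equal(as.character(label_candidate(cand)), "miRNA")

  # same hairpin, uniform read smear -> other (read-fraction rule alone)
  smear <- data.frame(offset = seq(0L, nchar(hp$sequence) - 21L, by = 7L),
                      length = 21L, count = 10L)
  cand2 <- make_candidate(hp$sequence, m, smear)
  expect_equal(as.character(label_candidate(cand2)), "other")

  # duplex reads present but diluted by cluster reads outside the window
  cand3 <- make_candidate(hp$sequence, m, precise,
                          cluster_count = sum(precise$count) * 4L)
  expect_equal(as.character(label_candidate(cand3)), "other")
})

test_that("match_known counts ungapped identities with a strict threshold", {
  ref <- c("UGGAAGCUUGGUCGAACAUCG", "ACGGAUCGGAUCGGAUCGGAU")
  # identical query
  r <- match_known(ref[1], ref)
  expect_equal(r$best_identity, 21L)
  expect_true(r$is_known)
  # exactly 18 identities is NOT known (strictly more than 18 required)
  mm3 <- chartr("ACGU", "CAUG", substr(ref[1], 19, 21))
  q18 <- paste0(substr(ref[1], 1, 18), mm3)
  r18 <- match_known(q18, ref[1])
  expect_equal(r18$best_identity, oracle_identity(q18, ref[1]))
  expect_equal(r18$best_identity, 18L)
  expect_false(r18$is_known)
  # brute-force oracle agreement on random queries
  set.seed(24)
  for (i in 1:20) {
    q <- random_rna(21)
    got <- match_known(q, ref)
    want <- max(vapply(ref, function(r) oracle_identity(q, r), 0L))
    expect_equal(got$best_identity, want)
    expect_equal(got$is_known, want > 18L)
  }
  expect_error(match_known("ACGU", character(0)), "non-empty")
})
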