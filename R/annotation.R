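#' Locate the miRNA* span pairing with a mature span
#'
#' Follows the standard Dicer-product geometry: the star strand pairs the
#' mature with a 2-nt 3' overhang on each side of the duplex. Writing
#' `p(i)` for the fold partner of mature base `i`, the star read span is
#' `[min(p) + 2, max(p) + 2]` over the paired mature bases (the uniform
#' consequence of the overhang on either arm), clipped to the sequence.
#'
#' @param fold a `fold_result`.
#' @param mature_span integer c(start, end), 1-based inclusive.
#' @return integer c(start, end) of the star span, or `integer(0)` when
#'   fewer than half of the mature bases have partners.
#' @export
locate_star <- function(fold, mature_span) {
  pt <- fold$pair_table
  idx <- mature_span[1]:mature_span[2]
  partners <- pt[idx]
  partners <- partners[partners > 0]
  if (length(partners) < length(idx) / 2) return(integer(0))
  n <- nchar(fold$sequence)
  c(max(1L, min(partners) + 2L), min(n, max(partners) + 2L))
}

#' Evaluate a miRNA/miRNA* duplex against Meyers-style criteria
#'
#' Counts, on the mature span, positions that are unpaired or paired
#' outside the star region (`n_mismatch`), and mature-side nucleotides in
#' asymmetric bulges (`n_asym_bulge_nt`): a maximal internal unpaired run
#' of u nt whose opposite-arm gap is shorter contributes all u
#' nucleotides. `has_secondary_stem` flags any duplex base whose partner
#' lies outside the contiguous opposite region, and `has_large_loop` any
#' internal unpaired stretch within the duplex longer than
#' `max_loop_run` nt. The duplex passes when
#' `n_mismatch <= max_mismatch`, `n_asym_bulge_nt <= max_asym`, and
#' neither structural flag is raised (defaults 5, 3, the quoted
#' annotation thresholds).
#'
#' Because the star span carries the 2-nt 3' overhang shift, partner
#' containment checks extend the opposing span by 2 nt on each side.
#'
#' @param fold a `fold_result`.
#' @param mature_span,star_span integer c(start, end), 1-based inclusive.
#' @param max_mismatch,max_asym,max_loop_run pass thresholds.
#' @return an object of class `duplex_report` with fields `star_span`,
#'   `n_mismatch`, `n_asym_bulge_nt`, `has_secondary_stem`,
#'   `has_large_loop`, `passes`.
#' @export
evaluate_duplex <- function(fold, mature_span, star_span,
                            max_mismatch = 5L, max_asym = 3L,
                            max_loop_run = 5L) {
  pt <- fold$pair_table
  n <- nchar(fold$sequence)
  m_idx <- mature_span[1]:mature_span[2]
  # the duplex core opposite the mature is the star READ span minus its
  # 2-nt 3' overhang (which belongs to the continuing lower stem)
  core <- if (length(star_span) == 2)
    c(max(1L, star_span[1] - 2L), max(1L, star_span[2] - 2L)) else integer(0)
  s_idx <- if (length(core)) core[1]:core[2] else integer(0)
  s_lo <- if (length(core)) max(1L, core[1] - 2L) else 0L
  s_hi <- if (length(core)) min(n, core[2] + 2L) else -1L
  m_lo <- max(1L, mature_span[1] - 2L)
  m_hi <- min(n, mature_span[2] + 2L)

  p_m <- pt[m_idx]
  in_star <- p_m >= s_lo & p_m <= s_hi
  mism <- p_m < 0 | !in_star
  n_mismatch <- sum(mism)

  # mature-side asymmetric bulge nucleotides: maximal internal unpaired
  # runs compared with the opposite-arm gap between the flanking partners
  unp <- p_m < 0
  n_asym <- 0L
  r <- rle(unp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (q in seq_along(r$values)) {
    if (!r$values[q]) next
    a <- starts[q]; b <- ends[q]
    if (a == 1L || b == length(m_idx)) next        # terminal, not a bulge
    pa <- p_m[a - 1L]; pb <- p_m[b + 1L]
    if (pa < 0 || pb < 0) next
    u <- b - a + 1L
    o <- abs(pa - pb) - 1L
    if (u > o) n_asym <- n_asym + u
  }

  has_secondary_stem <- any(p_m > 0 & !in_star)
  if (length(s_idx)) {
    p_s <- pt[s_idx]
    has_secondary_stem <- has_secondary_stem ||
      any(p_s > 0 & (p_s < m_lo | p_s > m_hi))
  }

  long_run <- function(p, span_len) {
    u <- p < 0
    rr <- rle(u)
    if (!any(rr$values)) return(FALSE)
    e <- cumsum(rr$lengths); s <- e - rr$lengths + 1L
    internal <- rr$values & s > 1L & e < span_len
    any(rr$lengths[internal] > max_loop_run)
  }
  has_large_loop <- long_run(p_m, length(m_idx)) ||
    (length(s_idx) > 0 && long_run(pt[s_idx], length(s_idx)))

  passes <- n_mismatch <= max_mismatch && n_asym <= max_asym &&
    !has_secondary_stem && !has_large_loop
  structure(list(star_span = star_span, n_mismatch = as.integer(n_mismatch),
                 n_asym_bulge_nt = n_asym,
                 has_secondary_stem = has_secondary_stem,
                 has_large_loop = has_large_loop, passes = passes),
            class = "duplex_report")
}

#' @export
print.duplex_report <- function(x, ...) {
  cat("duplex_report: mismatches ", x$n_mismatch, ", asymmetric-bulge nt ",
      x$n_asym_bulge_nt, ", secondary stem ", x$has_secondary_stem,
      ", large loop ", x$has_large_loop, " -> ",
      if (x$passes) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' Label a hairpin candidate as miRNA or other
#'
#' A candidate is called miRNA when (i) its mature/star duplex passes
#' [evaluate_duplex()] and (ii) reads at the duplex -- reads fully
#' contained in the mature span or the star span, each widened by
#' `slop` nt -- account for at least `min_duplex_fraction` of the read
#' count of the candidate's whole cluster (precise Dicer processing at
#' the locus; using the cluster total prevents a short window from
#' hiding a dispersed read smear outside it). Everything else, including
#' siRNA-like read smears over foldable regions, is labelled other.
#'
#' @param candidate a folded `precursor_candidate` (must have passed
#'   [select_hairpin_candidates()]).
#' @param min_duplex_fraction required duplex read fraction (default
#'   0.75).
#' @param slop positional tolerance (nt) for read containment.
#' @param ... thresholds forwarded to [evaluate_duplex()].
#' @return `"miRNA"` or `"other"`. The duplex report and the duplex read
#'   fraction are attached as attributes.
#' @export
label_candidate <- function(candidate, min_duplex_fraction = 0.75,
                            slop = 3L, ...) {
  if (is.null(candidate$fold))
    stop("candidate must be folded first (select_hairpin_candidates)")
  star <- locate_star(candidate$fold, candidate$mature_span)
  if (length(star) == 0)
    return(structure("other", duplex = NULL, duplex_fraction = NA_real_))
  rep <- evaluate_duplex(candidate$fold, candidate$mature_span, star, ...)
  reads <- candidate$mapped_reads
  rs <- reads$offset + 1L
  re <- reads$offset + reads$length
  contained <- function(span) rs >= span[1] - slop & re <= span[2] + slop
  total <- candidate$cluster_count %||% sum(reads$count)
  frac <- sum(reads$count[contained(candidate$mature_span) | contained(star)]) /
    total
  lab <- if (rep$passes && frac >= min_duplex_fraction) "miRNA" else "other"
  structure(lab, duplex = rep, duplex_fraction = frac)
}

#' Match a candidate mature sequence against known miRNAs
#'
#' Computes, for every reference sequence, the maximum number of
#' identical aligned bases over all ungapped offsets of the query against
#' the reference (no reverse complement), and reports the best identity.
#' A candidate is "known" when the best identity strictly exceeds
#' `min_matches` (default 18, i.e. more than 18 matches).
#'
#' @param query a mature sequence (RNA or DNA alphabet).
#' @param reference character vector (or `XStringSet`) of known mature
#'   miRNAs.
#' @param min_matches identity threshold; strict inequality.
#' @return list with `best_identity` (integer) and `is_known` (logical).
#' @export
match_known <- function(query, reference, min_matches = 18L) {
  if (length(reference) == 0) stop("reference must be non-empty")
  norm <- function(x) chartr("Uu", "Tt", toupper(as.character(x)))
  q <- strsplit(norm(query), "")[[1]]
  lq <- length(q)
  best <- 0L
  for (ref in norm(reference)) {
    r <- strsplit(ref, "")[[1]]
    lr <- length(r)
    for (off in (-(lq - 1L)):(lr - 1L)) {
      qi <- max(1L, 1L - off):min(lq, lr - off)
      if (length(qi) == 0) next
      best <- max(best, sum(q[qi] == r[qi + off]))
    }
  }
  list(best_identity = as.integer(best), is_known = best > min_matches)
}
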