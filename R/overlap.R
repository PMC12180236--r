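# Interval and anchor-pair intersection primitives. Internally everything is
# 0-based half-open; GRanges conversion adds 1 to starts. Overlap means >= 1
# shared bp (bedtools default).

as_granges0 <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]] + 1, end = df[[end]]))
}

snp_intervals <- function(snps) {
  tibble(chrom = snps$chrom, start = snps$pos - 1, end = snps$pos)
}

anchor_granges <- function(loops, which = c("A", "B"), slack = 0) {
  which <- match.arg(which)
  if (which == "A")
    gr <- as_granges0(loops, "chrom1", "start1", "end1")
  else
    gr <- as_granges0(loops, "chrom2", "start2", "end2")
  if (slack > 0) gr <- GenomicRanges::resize(
    gr, GenomicRanges::width(gr) + 2 * slack, fix = "center")
  gr
}

#' Intervals overlapping after symmetric expansion
#'
#' Reports every pair `(index_a, index_b)` for which interval `a[i]`,
#' expanded by `slack` bp on both sides, shares at least 1 bp with `b[j]`.
#'
#' @param a,b Interval tibbles with columns `chrom, start, end` (0-based
#'   half-open).
#' @param slack Non-negative expansion in bp applied to each side of `a`.
#' @return A tibble `(index_a, index_b)` sorted by `(index_a, index_b)`.
#' @export
intersect_with_slack <- function(a, b, slack = 0) {
  if (slack < 0) abort("slack must be >= 0")
  ga <- as_granges0(a)
  if (slack > 0) ga <- GenomicRanges::resize(
    ga, GenomicRanges::width(ga) + 2 * slack, fix = "center")
  hits <- find_overlaps_quiet(ga, as_granges0(b))
  out <- tibble(index_a = S4Vectors::queryHits(hits),
                index_b = S4Vectors::subjectHits(hits))
  arrange(out, .data$index_a, .data$index_b)
}

#' Per-anchor feature overlaps for loops
#'
#' bedtools `pairtobed`-style intersection: for each loop, which features
#' overlap anchor A and which overlap anchor B. A feature spanning both
#' anchors is reported for both.
#'
#' @param loops Loop tibble.
#' @param features Interval tibble (`chrom, start, end`).
#' @param slack Expansion in bp applied to each anchor side.
#' @return A tibble `(loop_index, feature_index, anchor)` with `anchor` in
#'   `{"A","B"}`, sorted.
#' @export
pair_feature_overlap <- function(loops, features, slack = 0) {
  if (slack < 0) abort("slack must be >= 0")
  gf <- as_granges0(features)
  res <- map(c("A", "B"), function(w) {
    hits <- find_overlaps_quiet(anchor_granges(loops, w, slack), gf)
    tibble(loop_index = S4Vectors::queryHits(hits),
           feature_index = S4Vectors::subjectHits(hits), anchor = w)
  })
  arrange(bind_rows(res), .data$loop_index, .data$anchor, .data$feature_index)
}

#' Loop vs region-pair overlaps
#'
#' bedtools `pairtopair`-style intersection: a loop matches a region pair
#' iff one member of the pair overlaps one anchor and the other member
#' overlaps the opposing anchor (both orientations are tested).
#'
#' @param loops Loop tibble.
#' @param pairs Tibble of region pairs with columns `chrom1, start1, end1,
#'   chrom2, start2, end2`.
#' @return A tibble `(loop_index, pair_index)`, distinct and sorted.
#' @export
pair_pair_overlap <- function(loops, pairs) {
  p1 <- as_granges0(pairs, "chrom1", "start1", "end1")
  p2 <- as_granges0(pairs, "chrom2", "start2", "end2")
  ga <- anchor_granges(loops, "A")
  gb <- anchor_granges(loops, "B")
  match_orient <- function(ha, hb) {
    a <- tibble(loop_index = S4Vectors::queryHits(ha),
                pair_index = S4Vectors::subjectHits(ha))
    b <- tibble(loop_index = S4Vectors::queryHits(hb),
                pair_index = S4Vectors::subjectHits(hb))
    dplyr::inner_join(a, b, by = c("loop_index", "pair_index"))
  }
  out <- bind_rows(
    match_orient(find_overlaps_quiet(ga, p1),
                 find_overlaps_quiet(gb, p2)),
    match_orient(find_overlaps_quiet(ga, p2),
                 find_overlaps_quiet(gb, p1)))
  arrange(distinct(out), .data$loop_index, .data$pair_index)
}

#' Recall of a truth peak set by a test peak set
#'
#' Fraction of truth peaks overlapped by at least one test peak after
#' expanding truth peaks by `slack` bp on both sides (default 1 kb).
#'
#' @param truth Non-empty peak/interval tibble (`chrom, start, end`).
#' @param test Peak/interval tibble.
#' @param slack Expansion in bp (default 1000).
#' @return Recall fraction in \eqn{[0, 1]}.
#' @export
peak_recall <- function(truth, test, slack = 1000) {
  if (nrow(truth) == 0) abort("recall undefined for empty truth set")
  hits <- intersect_with_slack(truth, test, slack = slack)
  length(unique(hits$index_a)) / nrow(truth)
}

#' Drop loops touching blacklisted regions
#'
#' Removes a loop when either anchor overlaps (>= 1 bp, no slack) any
#' blacklist interval. Half-open semantics: merely touching intervals do not
#' overlap.
#'
#' @param loops Loop tibble.
#' @param blacklist Interval tibble (`chrom, start, end`).
#' @return The filtered loop tibble.
#' @export
exclude_blacklisted <- function(loops, blacklist) {
  if (nrow(loops) == 0 || nrow(blacklist) == 0) return(loops)
  gb <- as_granges0(blacklist)
  hitA <- overlaps_any_quiet(anchor_granges(loops, "A"), gb)
  hitB <- overlaps_any_quiet(anchor_granges(loops, "B"), gb)
  loops[!(hitA | hitB), , drop = FALSE]
}

# findOverlaps warns when query and subject share no seqlevels; for genomic
# interval sets that is an ordinary empty result, not a user error.
find_overlaps_quiet <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject))
}

overlaps_any_quiet <- function(query, subject) {
  suppressWarnings(IRanges::overlapsAny(query, subject))
}
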