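# Conserved-anchor identification, GC-matched background sampling,
# representative-peak motif annotation, and the block-bootstrap motif-pair
# enrichment test (anchors shuffled uniformly within their chromosome).

#' Build the anchor universe of a loop set
#'
#' Collapses a loop table to its distinct anchors and re-expresses each loop
#' as a pair of anchor indices; the basis for motif annotation and the
#' block-bootstrap shuffle.
#'
#' @param loops Loop tibble.
#' @return A list with `anchors` (tibble `anchor_index, chrom, start, end`)
#'   and `loops` (tibble `anchor_a, anchor_b, chrom`).
#' @export
anchor_universe <- function(loops) {
  both <- bind_rows(
    tibble(chrom = loops$chrom1, start = loops$start1, end = loops$end1),
    tibble(chrom = loops$chrom2, start = loops$start2, end = loops$end2))
  anchors <- distinct(both) |>
    arrange(.data$chrom, .data$start, .data$end) |>
    mutate(anchor_index = row_number()) |>
    select("anchor_index", "chrom", "start", "end")
  key <- paste(anchors$chrom, anchors$start, anchors$end)
  ia <- match(paste(loops$chrom1, loops$start1, loops$end1), key)
  ib <- match(paste(loops$chrom2, loops$start2, loops$end2), key)
  list(anchors = anchors,
       loops = tibble(anchor_a = ia, anchor_b = ib, chrom = loops$chrom1))
}

#' Sample count needed for a conserved anchor
#'
#' @param n Number of samples in the set.
#' @param frac Conservation fraction (default 0.8).
#' @return `ceiling(frac * n)`, the minimum number of samples an anchor must
#'   appear in.
#' @export
conserved_threshold <- function(n, frac = 0.8) {
  if (n < 1 || frac <= 0 || frac > 1) abort("need n >= 1 and 0 < frac <= 1")
  as.integer(ceiling(frac * n))
}

#' Conserved loop anchors across a sample set
#'
#' An anchor is conserved when it participates in at least one loop in at
#' least `ceiling(frac * n)` of the `n` samples.
#'
#' @param anchor_sets Tibble of per-sample unique anchors with columns
#'   `sample_id, chrom, start, end` (all at one resolution).
#' @param frac Conservation fraction (default 0.8).
#' @return A list: `conserved` and `non_conserved` anchor tibbles
#'   (`chrom, start, end, n_samples`), plus `threshold` and `n_samples`.
#' @export
conserved_anchors <- function(anchor_sets, frac = 0.8) {
  n <- dplyr::n_distinct(anchor_sets$sample_id)
  thr <- conserved_threshold(n, frac)
  tab <- anchor_sets |>
    distinct(.data$sample_id, .data$chrom, .data$start, .data$end) |>
    count(.data$chrom, .data$start, .data$end, name = "n_samples") |>
    arrange(.data$chrom, .data$start)
  list(conserved = filter(tab, .data$n_samples >= thr),
       non_conserved = filter(tab, .data$n_samples < thr),
       threshold = thr, n_samples = n)
}

#' GC content of sequences
#' @param seqs Character vector of DNA sequences.
#' @return Fraction of G/C characters per sequence.
#' @export
gc_content <- function(seqs) {
  vapply(seqs, function(s) {
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    if (!length(v)) return(NA_real_)
    mean(v %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC-matched background sampling
#'
#' Pool sequences are assigned to GC-content quantile bins (0.5% quantiles
#' by default); for each foreground sequence one pool member is sampled from
#' the bin its GC content falls in (with replacement across draws). Empty
#' bins fall back to the nearest non-empty bin with a warning. Output size
#' equals the foreground size.
#'
#' @param foreground,pool Tibbles with a `seq` column (or character vectors
#'   of sequences).
#' @param bin_width Quantile bin width (default 0.005 = 0.5%).
#' @return The sampled background: a tibble of pool rows (with `gc` added),
#'   one per foreground sequence.
#' @export
gc_matched_background <- function(foreground, pool, bin_width = 0.005) {
  as_seq_tbl <- function(x) {
    if (is.character(x)) x <- tibble(seq = x)
    if (!"seq" %in% names(x)) abort("need a `seq` column")
    x
  }
  foreground <- as_seq_tbl(foreground); pool <- as_seq_tbl(pool)
  if (nrow(pool) < nrow(foreground))
    abort("pool must be at least as large as the foreground")
  fg_gc <- gc_content(foreground$seq)
  pool_gc <- gc_content(pool$seq)
  breaks <- unique(quantile(pool_gc, probs = seq(0, 1, by = bin_width),
                            names = FALSE))
  pool_bin <- findInterval(pool_gc, breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
  fg_bin <- findInterval(fg_gc, breaks, rightmost.closed = TRUE,
                         all.inside = TRUE)
  by_bin <- split(seq_along(pool_bin), pool_bin)
  filled <- sort(as.integer(names(by_bin)))
  n_fallback <- 0L
  idx <- vapply(fg_bin, function(b) {
    if (!as.character(b) %in% names(by_bin)) {
      b2 <- filled[which.min(abs(filled - b))]
      n_fallback <<- n_fallback + 1L
      b <- b2
    }
    cand <- by_bin[[as.character(b)]]
    cand[sample.int(length(cand), 1L)]
  }, integer(1))
  if (n_fallback > 0)
    warn(paste0(n_fallback, " foreground sequence(s) fell in an empty GC ",
                "bin; nearest non-empty bin used"))
  out <- pool[idx, , drop = FALSE]
  out$gc <- pool_gc[idx]
  out
}

#' Representative peak per anchor
#'
#' For each anchor with at least one overlapping peak (no slack), keeps the
#' peak with the highest `signal_value` (ties broken by leftmost start, then
#' lowest index). The representative peak set is deduplicated: one record
#' per peak even when it represents several anchors.
#'
#' @param anchors Anchor tibble (`anchor_index, chrom, start, end`).
#' @param peaks Peak tibble with `chrom, start, end, signal_value`.
#' @return A list: `assignment` (tibble `anchor_index, peak_index`) and
#'   `peaks` (deduplicated tibble of representative peaks with
#'   `peak_index`).
#' @export
representative_peaks <- function(anchors, peaks) {
  hits <- intersect_with_slack(
    select(anchors, "chrom", "start", "end"), peaks, slack = 0)
  if (nrow(hits) == 0)
    return(list(assignment = tibble(anchor_index = integer(),
                                    peak_index = integer()),
                peaks = mutate(peaks[0, ], peak_index = integer())))
  hits <- hits |>
    mutate(anchor_index = anchors$anchor_index[.data$index_a],
           peak_index = .data$index_b,
           signal_value = peaks$signal_value[.data$index_b],
           peak_start = peaks$start[.data$index_b]) |>
    group_by(.data$anchor_index) |>
    arrange(desc(.data$signal_value), .data$peak_start, .data$peak_index,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  assignment <- select(hits, "anchor_index", "peak_index") |>
    arrange(.data$anchor_index)
  reps <- peaks[sort(unique(assignment$peak_index)), , drop = FALSE]
  reps$peak_index <- sort(unique(assignment$peak_index))
  list(assignment = assignment, peaks = reps)
}

#' Annotate anchors with motifs via representative peaks
#'
#' A motif is assigned to an anchor when one of its occurrences overlaps
#' both the anchor and the anchor's representative peak. Anchors without a
#' representative peak receive the empty set.
#'
#' @param anchors Anchor tibble (`anchor_index, chrom, start, end`).
#' @param occurrences Motif occurrence tibble (`motif_id, chrom, start,
#'   end`, FIMO-style, already thresholded on q-value).
#' @param reps Output of [representative_peaks()].
#' @return A tibble `(anchor_index, motif_id)`, one row per assigned motif
#'   (set semantics).
#' @export
annotate_anchor_motifs <- function(anchors, occurrences, reps) {
  if (nrow(reps$assignment) == 0 || nrow(occurrences) == 0)
    return(tibble(anchor_index = integer(), motif_id = character()))
  withpk <- dplyr::inner_join(anchors, reps$assignment, by = "anchor_index")
  pk <- reps$peaks[match(withpk$peak_index, reps$peaks$peak_index), ]
  # clip the anchor to its representative peak: occurrences must hit both
  region <- tibble(chrom = withpk$chrom,
                   start = pmax(withpk$start, pk$start),
                   end = pmin(withpk$end, pk$end))
  keep <- region$start < region$end
  region <- region[keep, , drop = FALSE]
  withpk <- withpk[keep, , drop = FALSE]
  if (!nrow(region))
    return(tibble(anchor_index = integer(), motif_id = character()))
  hits <- intersect_with_slack(region, occurrences, slack = 0)
  tibble(anchor_index = withpk$anchor_index[hits$index_a],
         motif_id = occurrences$motif_id[hits$index_b]) |>
    distinct() |>
    arrange(.data$anchor_index, .data$motif_id)
}

annotation_codes <- function(annotation) {
  motifs <- sort(unique(annotation$motif_id))
  list(motifs = motifs,
       by_anchor = split(match(annotation$motif_id, motifs),
                         annotation$anchor_index))
}

anchor_sets_for <- function(idx, by_anchor) {
  out <- by_anchor[as.character(idx)]
  out[vapply(out, is.null, logical(1))] <- list(integer(0))
  unname(out)
}

#' Observed motif-pair counts across loops
#'
#' A loop contributes one count to the unordered pair (a, b) — self-pairs
#' allowed — iff `a` is annotated on one anchor and `b` on the other (either
#' orientation); each loop contributes at most once per pair.
#'
#' @param universe Output of [anchor_universe()].
#' @param annotation Tibble `(anchor_index, motif_id)` from
#'   [annotate_anchor_motifs()].
#' @return A tibble `(motif_a, motif_b, count)` with `motif_a <= motif_b`.
#' @export
observed_pair_counts <- function(universe, annotation) {
  if (nrow(annotation) == 0)
    return(tibble(motif_a = character(), motif_b = character(),
                  count = integer()))
  cod <- annotation_codes(annotation)
  res <- count_motif_pairs(
    anchor_sets_for(universe$loops$anchor_a, cod$by_anchor),
    anchor_sets_for(universe$loops$anchor_b, cod$by_anchor))
  tibble(motif_a = cod$motifs[res$motif_a],
         motif_b = cod$motifs[res$motif_b],
         count = res$count) |>
    arrange(.data$motif_a, .data$motif_b)
}

#' Block-bootstrap enrichment test for motif pairs
#'
#' Null model: in each simulation every loop's two anchors are replaced by
#' anchors drawn uniformly with replacement from the same chromosome's
#' anchor pool (annotations travel with the anchors) and pairs are
#' recounted. The empirical p-value for each observed pair is
#' `(1 + #{simulations with count >= observed}) / (1 + n_sims)` (add-one
#' estimator; set `add_one = FALSE` for the plain fraction).
#'
#' @param universe Output of [anchor_universe()] on blacklist-filtered
#'   loops.
#' @param annotation Tibble `(anchor_index, motif_id)`.
#' @param n_sims Number of simulations (default 100,000).
#' @param seed Integer seed; required for reproducibility.
#' @param add_one Use the add-one p-value estimator (default `TRUE`).
#' @return A tibble `(motif_a, motif_b, observed_count, p_empirical,
#'   n_sims)`, one row per observed pair.
#' @export
bootstrap_pair_enrichment <- function(universe, annotation, n_sims = 1e5,
                                      seed = NULL, add_one = TRUE) {
  obs <- observed_pair_counts(universe, annotation)
  if (nrow(obs) == 0)
    return(tibble(motif_a = character(), motif_b = character(),
                  observed_count = integer(), p_empirical = numeric(),
                  n_sims = integer()))
  if (!is.null(seed)) set.seed(seed)
  cod <- annotation_codes(annotation)
  motifs <- cod$motifs
  pa <- match(obs$motif_a, motifs); pb <- match(obs$motif_b, motifs)

  pool_by_chrom <- split(universe$anchors$anchor_index,
                         universe$anchors$chrom)
  degenerate <- names(pool_by_chrom)[lengths(pool_by_chrom) == 1L]
  if (length(degenerate))
    warn(paste0("chromosome(s) with a single anchor (degenerate shuffle): ",
                paste(degenerate, collapse = ", ")))
  loop_chrom <- universe$loops$chrom
  loops_by_chrom <- split(seq_along(loop_chrom), loop_chrom)

  n_loops <- nrow(universe$loops)
  exceed <- integer(nrow(obs))
  obs_counts <- obs$count
  for (s in seq_len(n_sims)) {
    new_a <- integer(n_loops); new_b <- integer(n_loops)
    for (chr in names(loops_by_chrom)) {
      li <- loops_by_chrom[[chr]]
      pool <- pool_by_chrom[[chr]]
      draws <- pool[sample.int(length(pool), 2L * length(li), replace = TRUE)]
      new_a[li] <- draws[seq_along(li)]
      new_b[li] <- draws[length(li) + seq_along(li)]
    }
    cnt <- count_given_pairs(anchor_sets_for(new_a, cod$by_anchor),
                             anchor_sets_for(new_b, cod$by_anchor), pa, pb)
    exceed <- exceed + (cnt >= obs_counts)
  }
  p <- if (add_one) (1 + exceed) / (1 + n_sims) else exceed / n_sims
  tibble(motif_a = obs$motif_a, motif_b = obs$motif_b,
         observed_count = obs$count, p_empirical = p,
         n_sims = as.integer(n_sims))
}

#' Restrict pairs to the top-k motifs and adjust p-values
#'
#' Motifs are ranked by how often they appear across the sample's observed
#' pairs (ties broken alphabetically); pairs are kept when BOTH members are
#' in the top `top_k` motifs, and Benjamini-Hochberg adjustment is applied
#' to the retained p-values only.
#'
#' @param results Pair-result tibble from [bootstrap_pair_enrichment()].
#' @param top_k Number of top motifs retained (default 50).
#' @return The retained rows with a `p_adjusted` column.
#' @export
filter_and_adjust <- function(results, top_k = 50) {
  if (nrow(results) == 0) return(mutate(results, p_adjusted = numeric(0)))
  freq <- c(results$motif_a, results$motif_b)
  tab <- sort(table(freq), decreasing = TRUE)
  ord <- names(tab)[order(-as.integer(tab), names(tab))]
  top <- head(ord, top_k)
  kept <- filter(results, .data$motif_a %in% top, .data$motif_b %in% top)
  mutate(kept, p_adjusted = p.adjust(.data$p_empirical, method = "BH"))
}

#' Cross-sample significance summary for motif pairs
#'
#' For each pair, the proportion of samples in which it is significant among
#' the samples where it was tested at all.
#'
#' @param per_sample Tibble with columns `sample_id, motif_a, motif_b,
#'   p_adjusted` (stacked per-sample results).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return A tibble `(motif_a, motif_b, n_tested, n_significant,
#'   proportion)`.
#' @export
cross_sample_summary <- function(per_sample, alpha = 0.05) {
  per_sample |>
    group_by(.data$motif_a, .data$motif_b) |>
    summarise(n_tested = dplyr::n_distinct(.data$sample_id),
              n_significant = dplyr::n_distinct(
                .data$sample_id[.data$p_adjusted <= alpha]),
              .groups = "drop") |>
    mutate(proportion = .data$n_significant / .data$n_tested)
}

#' Write foreground/background sequence sets for an external motif scanner
#'
#' Emits paired FASTA and BED files for the conserved-anchor foreground and
#' a GC-matched background so that 1D motif enrichment can be run with an
#' external tool; the enrichment scan itself is not performed here.
#'
#' @param foreground,background Tibbles with `chrom, start, end, seq`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four file paths written.
#' @export
export_enrichment_inputs <- function(foreground, background, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort("Biostrings is required to write FASTA output")
  write_set <- function(df, stem) {
    bed <- file.path(dir, paste0(stem, ".bed"))
    fa <- file.path(dir, paste0(stem, ".fa"))
    nm <- paste0(df$chrom, ":", format_coord(df$start), "-",
                 format_coord(df$end))
    utils::write.table(
      data.frame(df$chrom, format_coord(df$start), format_coord(df$end)),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    seqs <- Biostrings::DNAStringSet(df$seq)
    names(seqs) <- nm
    Biostrings::writeXStringSet(seqs, fa)
    c(bed, fa)
  }
  invisible(c(write_set(foreground, "foreground"),
              write_set(background, "background")))
}
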