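test_that("conserved-anchor thresholds use the ceiling rule", {
  expect_equal(conserved_threshold(54), 44L)
  expect_equal(conserved_threshold(27), 22L)
  expect_equal(conserved_threshold(11), 9L)
  # boundary: anchor in exactly ceil(0.8 n) - 1 samples is excluded
  n <- 10
  thr <- conserved_threshold(n)  # 8
  sets <- dplyr::bind_rows(lapply(seq_len(n), function(s) {
    tibble::tibble(sample_id = paste0("s", s),
                   chrom = "c1",
                   start = c(0, 5000), end = c(5000, 10000))[
                     seq_len(1 + (s <= thr - 1)), ]
  }))
  # anchor 0-5000 in all 10 samples; anchor 5000-10000 in thr-1 = 7 samples
  res <- conserved_anchors(sets)
  expect_equal(res$conserved$start, 0)
  expect_equal(res$non_conserved$start, 5000)
  expect_equal(res$threshold, thr)
})

test_that("GC-matched sampling draws from the foreground's GC bins", {
  fg <- strrep("GCGCGCGCGC", 5)                       # GC = 1.0? no: G/C only
  fg <- rep(paste0(strrep("GC", 25), strrep("AT", 25)), 20)  # GC = 0.5
  pool <- c(rep(paste0(strrep("GC", 25), strrep("AT", 25)), 40),  # 0.5
            rep(paste0(strrep("GC", 45), strrep("AT", 5)), 40))   # 0.9
  set.seed(3)
  bg <- gc_matched_background(fg, pool)
  expect_equal(nrow(bg), length(fg))
  expect_true(all(abs(bg$gc - 0.5) < 1e-9))
})

test_that("sampled background matches foreground GC better than the pool", {
  set.seed(11)
  mk <- function(gc, n, len = 200) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
                   prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
            collapse = "")
    }, "")
  }
  fg <- mk(0.6, 60)
  pool <- c(mk(0.4, 150), mk(0.6, 150))
  wins <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    bg <- gc_matched_background(fg, pool)
    ks_bg <- suppressWarnings(
      ks.test(gc_content(fg), bg$gc)$statistic)
    ks_pool <- suppressWarnings(
      ks.test(gc_content(fg), gc_content(pool))$statistic)
    wins <- wins + (ks_bg < ks_pool)
  }
  expect_gt(wins, 15)
})

test_that("representative peaks take max signal with deterministic ties", {
  anchors <- tibble::tibble(anchor_index = 1:2, chrom = "c1",
                            start = c(0, 10000), end = c(5000, 15000))
  peaks <- tibble::tibble(chrom = "c1",
                          start = c(100, 2000, 10100, 10050),
                          end = c(600, 2500, 10600, 10550),
                          signal_value = c(5, 9, 4, 4))
  rp <- representative_peaks(anchors, peaks)
  expect_equal(rp$assignment$peak_index, c(2L, 4L))  # max; tie -> leftmost
  # one peak representing two anchors appears once in the dedup set
  anchors2 <- tibble::tibble(anchor_index = 1:2, chrom = "c1",
                             start = c(0, 400), end = c(500, 1000))
  peaks2 <- tibble::tibble(chrom = "c1", start = 300, end = 700,
                           signal_value = 8)
  rp2 <- representative_peaks(anchors2, peaks2)
  expect_equal(nrow(rp2$assignment), 2L)
  expect_equal(nrow(rp2$peaks), 1L)
  # random fixture vs brute-force max per anchor
  set.seed(5)
  ra <- tibble::tibble(anchor_index = 1:30, chrom = "c1",
                       start = (0:29) * 5000)
  ra$end <- ra$start + 5000
  rps <- random_intervals(60, chroms = "c1", max_pos = 150000,
                          max_len = 2000)
  rps$signal_value <- round(runif(60, 1, 100), 3)
  got <- representative_peaks(ra, rps)
  for (i in ra$anchor_index) {
    ov <- which(rps$start < ra$end[i] & ra$start[i] < rps$end)
    if (!length(ov)) {
      expect_false(i %in% got$assignment$anchor_index)
    } else {
      best <- ov[order(-rps$signal_value[ov], rps$start[ov])][1]
      expect_equal(
        got$assignment$peak_index[got$assignment$anchor_index == i], best)
    }
  }
})

test_that("anchor motif annotation requires the representative peak", {
  anchors <- tibble::tibble(anchor_index = 1:2, chrom = "c1",
                            start = c(0, 10000), end = c(5000, 15000))
  peaks <- tibble::tibble(chrom = "c1", start = 1000, end = 2000,
                          signal_value = 5)
  occ <- tibble::tibble(motif_id = c("MX", "MY"), chrom = "c1",
                        start = c(1200, 11000), end = c(1210, 11010))
  rp <- representative_peaks(anchors, peaks)
  ann <- annotate_anchor_motifs(anchors, occ, rp)
  expect_equal(ann$anchor_index, 1L)   # anchor 2 has no peak -> empty set
  expect_equal(ann$motif_id, "MX")
})

test_that("observed pair counting is per-loop and unordered with self-pairs", {
  loops <- loops_from_edges(cbind(1, 2))
  uni <- anchor_universe(loops)
  ann <- tibble::tibble(anchor_index = c(1, 1, 2),
                        motif_id = c("X", "Y", "X"))
  got <- observed_pair_counts(uni, ann)
  expect_equal(got, tibble::tibble(motif_a = c("X", "X"),
                                   motif_b = c("X", "Y"),
                                   count = c(1L, 1L)))
  # random fixture vs brute-force double loop
  set.seed(21)
  ms <- synth_motif_scenario(n_loops = 100, n_motifs = 8, seed = 6)
  got2 <- observed_pair_counts(ms$universe, ms$annotation)
  sets <- split(ms$annotation$motif_id, ms$annotation$anchor_index)
  counts <- list()
  for (i in seq_len(nrow(ms$universe$loops))) {
    a <- sets[[as.character(ms$universe$loops$anchor_a[i])]]
    b <- sets[[as.character(ms$universe$loops$anchor_b[i])]]
    if (is.null(a) || is.null(b)) next
    prs <- unique(apply(expand.grid(a, b), 1, function(r)
      paste(sort(r), collapse = "|")))
    for (p in prs) counts[[p]] <- (counts[[p]] %||% 0L) + 1L
  }
  got_keys <- paste(got2$motif_a, got2$motif_b, sep = "|")
  expect_setequal(got_keys, names(counts))
  expect_equal(got2$count[match(names(counts), got_keys)],
               unlist(counts, use.names = FALSE))
})

test_that("shuffle-invariant annotation yields p = 1 everywhere", {
  loops <- loops_from_edges(cbind(1:4, 5:8))
  uni <- anchor_universe(loops)
  ann <- tidyr::expand_grid(anchor_index = uni$anchors$anchor_index,
                            motif_id = c("X", "Y"))
  res <- bootstrap_pair_enrichment(uni, ann, n_sims = 50, seed = 4)
  expect_true(all(res$p_empirical == 1))
})

test_that("bootstrap is bit-reproducible under a fixed seed", {
  ms <- synth_motif_scenario(n_loops = 80, n_motifs = 6, seed = 9)
  r1 <- bootstrap_pair_enrichment(ms$universe, ms$annotation,
                                  n_sims = 100, seed = 42)
  r2 <- bootstrap_pair_enrichment(ms$universe, ms$annotation,
                                  n_sims = 100, seed = 42)
  expect_identical(r1, r2)
  r3 <- bootstrap_pair_enrichment(ms$universe, ms$annotation,
                                  n_sims = 100, seed = 43)
  expect_false(identical(r1$p_empirical, r3$p_empirical))
})

test_that("top-k filtering and BH adjustment match hand computation", {
  res <- tibble::tibble(motif_a = c("A", "A", "B", "C"),
                        motif_b = c("A", "B", "C", "D"),
                        observed_count = c(5L, 4L, 3L, 2L),
                        p_empirical = c(0.001, 0.01, 0.02, 0.8),
                        n_sims = 1000L)
  adj <- filter_and_adjust(res, top_k = 50)
  expect_equal(adj$p_adjusted, bh_oracle(res$p_empirical))
  expect_equal(adj$p_adjusted, c(0.004, 0.02, 0.8 / 30, 0.8),
               tolerance = 1e-12)
  all1 <- dplyr::mutate(res, p_empirical = 1)
  expect_true(all(filter_and_adjust(all1)$p_adjusted == 1))
  # top-k restriction: keep pairs with BOTH members in the top-k motifs
  adj2 <- filter_and_adjust(res, top_k = 2)  # top motifs by frequency: A, B
  expect_equal(nrow(adj2), 2L)
  expect_true(all(adj2$motif_a %in% c("A", "B") &
                    adj2$motif_b %in% c("A", "B")))
})

test_that("cross-sample proportions exclude samples where a pair was untested", {
  per_sample <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s1", "s2"),
    motif_a = c("X", "X", "X", "Y", "Y"),
    motif_b = c("Z", "Z", "Z", "Z", "Z"),
    p_adjusted = c(0.01, 0.2, 0.03, 0.04, 0.01))
  cs <- cross_sample_summary(per_sample)
  expect_equal(cs$proportion[cs$motif_a == "X"], 2 / 3)
  expect_equal(cs$n_tested[cs$motif_a == "Y"], 2L)  # s3 never tested Y-Z
  expect_equal(cs$proportion[cs$motif_a == "Y"], 1)
})
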