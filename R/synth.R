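# Seeded synthetic-data generators. Defaults emulate the study conditions:
# FitHiChIP-style loops on a 5 kb grid with spans in [20 kb, 2 Mb] under a
# power-law distance decay, q-values from a significant/background mixture,
# and a compact 2-chromosome 10 Mb genome that keeps tests fast while
# leaving room for distance strata. Every generator returns truth records
# sufficient to compute the expected downstream answer.

#' Default synthetic genome
#' @return A chrom.sizes tibble: two chromosomes of 10 Mb.
#' @export
synth_chrom_sizes <- function() {
  tibble(chrom = c("chrS1", "chrS2"), length = c(1e7, 1e7))
}

#' Generate synthetic loops with distance decay
#'
#' Anchors sit on the resolution grid; spans are sampled proportional to
#' `d^(-alpha)` truncated to `[min_span, max_span]` (FitHiChIP's 20 kb-2 Mb
#' window by default); q-values come from a two-component mixture
#' (significant: `10^-U(2.5, 12)`; background: `U(0.011, 1)`).
#'
#' @param n_loops Number of loops.
#' @param chrom_sizes chrom.sizes tibble (default [synth_chrom_sizes()]).
#' @param resolution Bin size in bp (default 5000).
#' @param alpha Distance-decay exponent (> 0, default 1).
#' @param sig_frac Fraction of loops drawn from the significant q-value
#'   component (default 0.8).
#' @param min_span,max_span Span truncation in bp (defaults 20 kb, 2 Mb).
#' @param sample_id Sample id stamped on the loops.
#' @param seed Integer seed.
#' @param disjoint_anchors If `TRUE`, every anchor bin is used at most once
#'   across the whole loop set (needed by planted-scenario bookkeeping).
#' @return A list: `loops` (loop tibble) and `truth` (tibble with
#'   `is_significant` and the sampled spans).
#' @export
synth_loops <- function(n_loops = 200, chrom_sizes = synth_chrom_sizes(),
                        resolution = 5000, alpha = 1, sig_frac = 0.8,
                        min_span = 20000, max_span = 2e6,
                        sample_id = "synthS1", seed = 1,
                        disjoint_anchors = FALSE) {
  if (alpha <= 0) abort("alpha must be > 0")
  if (max(chrom_sizes$length) < min_span + 2 * resolution)
    abort("chromosomes too short for the minimum span")
  set.seed(seed)
  spans_grid <- seq(min_span, min(max_span, max(chrom_sizes$length) / 2),
                    by = resolution)
  p_span <- spans_grid^(-alpha); p_span <- p_span / sum(p_span)
  out <- vector("list", n_loops)
  used <- character(0)
  i <- 1L; tries <- 0L
  while (i <= n_loops) {
    tries <- tries + 1L
    if (tries > 50L * n_loops) abort("could not place loops (genome too small)")
    ci <- sample.int(nrow(chrom_sizes), 1L,
                     prob = chrom_sizes$length / sum(chrom_sizes$length))
    chrom <- chrom_sizes$chrom[ci]; clen <- chrom_sizes$length[ci]
    span <- sample(spans_grid, 1L, prob = p_span)
    max_start <- clen - span - resolution
    if (max_start < 0) next
    s1 <- sample.int(max_start %/% resolution + 1L, 1L) - 1L
    s1 <- s1 * resolution
    s2 <- s1 + span
    if (disjoint_anchors) {
      k <- c(paste(chrom, s1), paste(chrom, s2))
      if (any(k %in% used)) next
      used <- c(used, k)
    }
    out[[i]] <- tibble(chrom1 = chrom, start1 = s1, end1 = s1 + resolution,
                       chrom2 = chrom, start2 = s2, end2 = s2 + resolution)
    i <- i + 1L
  }
  loops <- bind_rows(out)
  is_sig <- runif(n_loops) < sig_frac
  q <- ifelse(is_sig, 10^(-runif(n_loops, 2.5, 12)),
              runif(n_loops, 0.011, 1))
  loops$q_value <- q
  loops$resolution <- resolution
  loops$sample_id <- sample_id
  list(loops = loops,
       truth = tibble(is_significant = is_sig,
                      span = loops$start2 - loops$start1))
}

#' Generate a planted SGL scenario
#'
#' Produces loops with pairwise-disjoint anchors, SNPs and genes such that
#' exactly `planted` (SNP, gene, loop) triples satisfy the opposing-anchor
#' rule. Distractors include loops carrying a SNP and a TSS in the SAME
#' anchor (rule violators) and SNPs/genes placed outside every anchor.
#'
#' @param n_loops Number of loops (default 120).
#' @param planted Number of planted SGL triples (default 25; must be
#'   `<= n_loops`).
#' @param n_violators Loops given a same-anchor SNP+TSS pair (default 5).
#' @param n_background Background SNPs and genes outside all anchors
#'   (default 30 each).
#' @param seed Integer seed.
#' @param ... Passed to [synth_loops()].
#' @return A list: `loops`, `snps`, `genes`, and `truth` (tibble of the
#'   planted rsid/gene_id/loop coordinates).
#' @export
synth_sgl_scenario <- function(n_loops = 120, planted = 25, n_violators = 5,
                               n_background = 30, seed = 1, ...) {
  if (planted > n_loops) abort("planted must be <= n_loops")
  gl <- synth_loops(n_loops = n_loops, seed = seed,
                    disjoint_anchors = TRUE, ...)
  loops <- gl$loops
  set.seed(seed + 1L)
  res <- loops$resolution[1]
  mid <- function(s) s + res %/% 2

  planted_idx <- seq_len(planted)
  snps <- tibble(rsid = paste0("rsP", planted_idx),
                 chrom = loops$chrom1[planted_idx],
                 pos = mid(loops$start1[planted_idx]) + 1,  # 1-based
                 posterior_prob = runif(planted),
                 study_id = "synth_study", disease = "synthD")
  genes <- tibble(gene_id = paste0("GP", planted_idx),
                  gene_name = paste0("GeneP", planted_idx),
                  chrom = loops$chrom2[planted_idx],
                  start = mid(loops$start2[planted_idx]),
                  end = mid(loops$start2[planted_idx]) + 2000,
                  strand = "+")

  vio_idx <- seq_len(n_violators) + planted
  vio_idx <- vio_idx[vio_idx <= n_loops]
  if (length(vio_idx)) {
    snps <- bind_rows(snps, tibble(
      rsid = paste0("rsV", vio_idx), chrom = loops$chrom1[vio_idx],
      pos = loops$start1[vio_idx] + 2, posterior_prob = runif(length(vio_idx)),
      study_id = "synth_study", disease = "synthD"))
    genes <- bind_rows(genes, tibble(
      gene_id = paste0("GV", vio_idx), gene_name = paste0("GeneV", vio_idx),
      chrom = loops$chrom1[vio_idx],
      start = loops$start1[vio_idx] + res %/% 4,
      end = loops$start1[vio_idx] + res %/% 4 + 1000, strand = "+"))
  }

  # background entities in bins untouched by any anchor
  anchor_key <- c(paste(loops$chrom1, loops$start1),
                  paste(loops$chrom2, loops$start2))
  cs <- synth_chrom_sizes()
  free_bins <- function(n) {
    out <- tibble(chrom = character(0), start = numeric(0))
    while (nrow(out) < n) {
      ci <- sample.int(nrow(cs), 1L)
      s <- (sample.int(cs$length[ci] %/% res - 1L, 1L) - 1L) * res
      if (!paste(cs$chrom[ci], s) %in% anchor_key)
        out <- bind_rows(out, tibble(chrom = cs$chrom[ci], start = s))
    }
    out
  }
  if (n_background > 0) {
    fb1 <- free_bins(n_background); fb2 <- free_bins(n_background)
    snps <- bind_rows(snps, tibble(
      rsid = paste0("rsB", seq_len(n_background)), chrom = fb1$chrom,
      pos = fb1$start + 10, posterior_prob = runif(n_background),
      study_id = "synth_study", disease = "synthD"))
    genes <- bind_rows(genes, tibble(
      gene_id = paste0("GB", seq_len(n_background)),
      gene_name = paste0("GeneB", seq_len(n_background)),
      chrom = fb2$chrom, start = fb2$start + 10, end = fb2$start + 1500,
      strand = sample(c("+", "-"), n_background, replace = TRUE)))
  }

  truth <- tibble(rsid = paste0("rsP", planted_idx),
                  gene_id = paste0("GP", planted_idx),
                  chrom = loops$chrom1[planted_idx],
                  start1 = loops$start1[planted_idx],
                  start2 = loops$start2[planted_idx])
  list(loops = loops, snps = snps, genes = genes, truth = truth)
}

#' Generate a planted motif-pair scenario
#'
#' Baseline: each motif is present on each anchor independently with
#' probability `motif_freq`. Planted pairs are additionally forced onto
#' opposing anchors of randomly chosen loops so that their expected loop
#' count is about `multiplier` times the independence expectation
#' (`2 * motif_freq^2` per loop). `multiplier = 1` plants nothing and
#' yields an exact null.
#'
#' @param n_loops Number of loops (default 300).
#' @param n_motifs Number of motifs (>= 2, default 20).
#' @param motif_freq Per-anchor baseline presence probability (default
#'   0.15).
#' @param planted Optional tibble `(motif_a, motif_b, multiplier)`.
#' @param seed Integer seed.
#' @param ... Passed to [synth_loops()].
#' @return A list: `loops`, `universe` ([anchor_universe()]), `annotation`
#'   (tibble `anchor_index, motif_id`) and `truth` (planted pairs with
#'   expected counts).
#' @export
synth_motif_scenario <- function(n_loops = 300, n_motifs = 20,
                                 motif_freq = 0.15, planted = NULL,
                                 seed = 1, ...) {
  if (n_motifs < 2) abort("need at least 2 motifs")
  gl <- synth_loops(n_loops = n_loops, seed = seed, ...)
  uni <- anchor_universe(gl$loops)
  set.seed(seed + 1L)
  motifs <- sprintf("M%02d", seq_len(n_motifs))
  n_anchor <- nrow(uni$anchors)
  present <- matrix(runif(n_anchor * n_motifs) < motif_freq,
                    nrow = n_anchor)
  idx <- which(present, arr.ind = TRUE)
  annotation <- tibble(anchor_index = uni$anchors$anchor_index[idx[, 1]],
                       motif_id = motifs[idx[, 2]])
  truth <- tibble(motif_a = character(), motif_b = character(),
                  multiplier = numeric(), expected_extra = numeric())
  if (!is.null(planted) && nrow(planted) > 0) {
    for (r in seq_len(nrow(planted))) {
      m <- planted$multiplier[r]
      if (m < 1) abort("multiplier must be >= 1")
      base_expect <- 2 * motif_freq^2 * n_loops
      n_extra <- round((m - 1) * base_expect)
      if (n_extra > 0) {
        li <- sample.int(n_loops, min(n_extra, n_loops))
        annotation <- bind_rows(
          annotation,
          tibble(anchor_index = uni$loops$anchor_a[li],
                 motif_id = planted$motif_a[r]),
          tibble(anchor_index = uni$loops$anchor_b[li],
                 motif_id = planted$motif_b[r]))
      }
      truth <- bind_rows(truth, tibble(
        motif_a = min(planted$motif_a[r], planted$motif_b[r]),
        motif_b = max(planted$motif_a[r], planted$motif_b[r]),
        multiplier = m, expected_extra = n_extra))
    }
  }
  annotation <- distinct(annotation) |>
    arrange(.data$anchor_index, .data$motif_id)
  list(loops = gl$loops, universe = uni, annotation = annotation,
       truth = truth)
}

#' Generate a contact window with planted center enrichment
#'
#' Symmetric Poisson counts with mean `base * (|i-j|+1)^(-alpha)`; planted
#' loop pixels have their mean multiplied by `enrichment`. A companion 1D
#' signal carries a planted contiguous high block on a smooth noise floor
#' for spatial-autocorrelation tests.
#'
#' @param n_bins Number of bins (default 200).
#' @param resolution Bin size in bp (default 5000).
#' @param alpha Decay exponent (default 0.3).
#' @param base Count scale at distance 0 (default 100).
#' @param enrichment Multiplier on planted pixels (>= 1, default 1).
#' @param n_planted Number of planted loop pixels (default 30).
#' @param min_sep_bins Minimum |i-j| of planted pixels; default `NULL`
#'   picks `max(10, n_bins %/% 3)`. At the default window size this puts
#'   planted pixels at separations where the decay background varies by
#'   only a few percent across an APA window, so a planted enrichment is
#'   identifiable.
#' @param block Integer range of bins for the high signal block (default
#'   81:110).
#' @param block_height Added signal height on the block (default 3).
#' @param seed Integer seed.
#' @return A list: `mat`, `signal`, `loop_bins` (tibble `bin_a, bin_b`),
#'   `resolution`, `enrichment`.
#' @export
synth_contact_window <- function(n_bins = 200, resolution = 5000,
                                 alpha = 0.3, base = 100, enrichment = 1,
                                 n_planted = 30, min_sep_bins = NULL,
                                 block = 81:110, block_height = 3,
                                 seed = 1) {
  if (enrichment < 1) abort("enrichment must be >= 1")
  set.seed(seed)
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  mu <- base * (d + 1)^(-alpha)
  w <- floor(30000 / resolution)
  lo <- w + 1; hi <- n_bins - w
  if (is.null(min_sep_bins)) min_sep_bins <- max(10L, n_bins %/% 3L)
  max_jitter <- max(1L, min(40L, hi - lo - min_sep_bins - 1L))
  if (hi - min_sep_bins - max_jitter <= lo)
    abort("n_bins too small for the planted separations")
  cand_a <- sample(seq(lo, hi - min_sep_bins - max_jitter), n_planted,
                   replace = TRUE)
  cand_b <- cand_a + min_sep_bins +
    sample.int(max_jitter, n_planted, replace = TRUE)
  loop_bins <- distinct(tibble(bin_a = cand_a, bin_b = cand_b))
  mu[cbind(loop_bins$bin_a, loop_bins$bin_b)] <-
    mu[cbind(loop_bins$bin_a, loop_bins$bin_b)] * enrichment
  mu[cbind(loop_bins$bin_b, loop_bins$bin_a)] <-
    mu[cbind(loop_bins$bin_a, loop_bins$bin_b)]
  up <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, n_bins, n_bins)
  counts[up] <- rpois(sum(up), mu[up])
  counts <- counts + t(counts) - diag(diag(counts))
  noise <- as.numeric(stats::filter(rnorm(n_bins + 20), rep(1 / 5, 5),
                                    sides = 2))
  noise <- noise[11:(10 + n_bins)]
  noise[is.na(noise)] <- 0
  signal <- 1 + 0.3 * noise
  block <- block[block >= 1 & block <= n_bins]
  signal[block] <- signal[block] + block_height
  list(mat = counts, signal = signal, loop_bins = loop_bins,
       resolution = resolution, enrichment = enrichment)
}

#' Generate a peak-recall scenario with known recall
#'
#' Truth peaks are spaced far apart; a chosen fraction get a test peak
#' within the slack window, the rest have their nearest test peak placed
#' beyond reach.
#'
#' @param n_truth Number of truth peaks (default 100).
#' @param frac_recoverable Fraction with a recovering test peak (default
#'   0.7).
#' @param slack Recall slack in bp (default 1000).
#' @param seed Integer seed.
#' @return A list: `truth`, `test` (peak tibbles) and `expected_recall`.
#' @export
synth_peak_scenario <- function(n_truth = 100, frac_recoverable = 0.7,
                                slack = 1000, seed = 1) {
  set.seed(seed)
  gap <- 20000
  start <- seq_len(n_truth) * gap
  width <- 400
  truth <- tibble(chrom = "chrS1", start = start, end = start + width,
                  name = paste0("t", seq_len(n_truth)),
                  score = 0, strand = ".",
                  signal_value = round(runif(n_truth, 1, 50), 2),
                  p_value = -1, q_value = -1, peak = -1)
  n_rec <- round(frac_recoverable * n_truth)
  rec <- sort(sample.int(n_truth, n_rec))
  test_rec <- tibble(chrom = "chrS1",
                     start = truth$start[rec] + width + slack - 100,
                     end = truth$start[rec] + width + slack - 100 + 200)
  miss <- setdiff(seq_len(n_truth), rec)
  test_miss <- tibble(chrom = "chrS1",
                      start = truth$end[miss] + slack + 500,
                      end = truth$end[miss] + slack + 700)
  test <- bind_rows(test_rec, test_miss) |>
    mutate(name = paste0("p", row_number()), score = 0, strand = ".",
           signal_value = round(runif(n(), 1, 50), 2), p_value = -1,
           q_value = -1, peak = -1) |>
    arrange(.data$start)
  list(truth = truth, test = test, expected_recall = n_rec / n_truth)
}

#' Write a synthetic scenario to a directory of standard-format files
#'
#' @param scenario One of `"loops"`, `"sgl"`, `"motif"`, `"window"`,
#'   `"peaks"`.
#' @param dir Output directory (created).
#' @param seed Integer seed.
#' @param ... Passed to the underlying generator.
#' @return Invisibly, the list of files written (plus `truth.json`).
#' @export
write_scenario <- function(scenario = c("loops", "sgl", "motif", "window",
                                        "peaks"),
                           dir, seed = 1, ...) {
  scenario <- match.arg(scenario)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  add <- function(p) files <<- c(files, p)
  truth <- NULL
  if (scenario == "loops") {
    g <- synth_loops(seed = seed, ...)
    add(write_bedpe(g$loops, file.path(dir, "loops.bedpe")))
    truth <- g$truth
  } else if (scenario == "sgl") {
    g <- synth_sgl_scenario(seed = seed, ...)
    add(write_bedpe(g$loops, file.path(dir, "loops.bedpe")))
    readr::write_tsv(g$snps, file.path(dir, "snps.tsv"))
    readr::write_tsv(g$genes, file.path(dir, "genes.tsv"))
    add(file.path(dir, c("snps.tsv", "genes.tsv")))
    truth <- g$truth
  } else if (scenario == "motif") {
    g <- synth_motif_scenario(seed = seed, ...)
    add(write_bedpe(g$loops, file.path(dir, "loops.bedpe")))
    readr::write_tsv(g$annotation, file.path(dir, "anchor_motifs.tsv"))
    add(file.path(dir, "anchor_motifs.tsv"))
    truth <- g$truth
  } else if (scenario == "window") {
    g <- synth_contact_window(seed = seed, ...)
    add(write_contacts(g$mat, file.path(dir, "contacts.tsv")))
    readr::write_tsv(tibble(bin = seq_along(g$signal), signal = g$signal),
                     file.path(dir, "signal.tsv"))
    readr::write_tsv(g$loop_bins, file.path(dir, "loop_bins.tsv"))
    add(file.path(dir, c("signal.tsv", "loop_bins.tsv")))
    truth <- list(loop_bins = g$loop_bins, enrichment = g$enrichment)
  } else {
    g <- synth_peak_scenario(seed = seed, ...)
    add(write_narrowpeak(g$truth, file.path(dir, "truth.narrowPeak")))
    add(write_narrowpeak(g$test, file.path(dir, "test.narrowPeak")))
    truth <- list(expected_recall = g$expected_recall)
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  add(file.path(dir, "truth.json"))
  invisible(files)
}
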