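# SNP-to-gene link (SGL) mapping: a loop becomes an SGL when one anchor
# contains a SNP and the opposing anchor contains a gene TSS (GWAS mode
# crosses SNPs with all TSSs; eQTL mode preserves the SNP-gene pairing).

#' Transcription start sites from gene records
#'
#' Plus-strand genes take their TSS at the gene start, minus-strand genes at
#' the gene end; each TSS is a width-1 interval (0-based half-open).
#'
#' @param genes Gene tibble (`gene_id, gene_name, chrom, start, end,
#'   strand`).
#' @return A tibble `(gene_id, gene_name, chrom, start, end, strand)` of
#'   width-1 TSS intervals.
#' @export
tss_from_genes <- function(genes) {
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  pos <- if_else(genes$strand == "+", genes$start, genes$end - 1)
  tibble(gene_id = genes$gene_id,
         gene_name = if ("gene_name" %in% names(genes)) genes$gene_name
                     else genes$gene_id,
         chrom = genes$chrom, start = pos, end = pos + 1,
         strand = genes$strand)
}

sgl_row_template <- function() {
  tibble(rsid = character(), gene_id = character(), gene_name = character(),
         chrom = character(), start1 = numeric(), end1 = numeric(),
         start2 = numeric(), end2 = numeric(), q_value = numeric(),
         resolution = numeric(), sample_id = character(),
         snp_anchor = character(), study_id = character(),
         disease = character())
}

sgl_from_indices <- function(loops, snps, tss, snp_idx, tss_idx, loop_idx,
                             snp_anchor) {
  tibble(
    rsid = snps$rsid[snp_idx],
    gene_id = tss$gene_id[tss_idx],
    gene_name = tss$gene_name[tss_idx],
    chrom = loops$chrom1[loop_idx],
    start1 = loops$start1[loop_idx], end1 = loops$end1[loop_idx],
    start2 = loops$start2[loop_idx], end2 = loops$end2[loop_idx],
    q_value = loops$q_value[loop_idx],
    resolution = loops$resolution[loop_idx],
    sample_id = loops$sample_id[loop_idx],
    snp_anchor = snp_anchor,
    study_id = if ("study_id" %in% names(snps))
      as.character(snps$study_id[snp_idx]) else NA_character_,
    disease = if ("disease" %in% names(snps))
      as.character(snps$disease[snp_idx]) else NA_character_)
}

#' Map GWAS SNPs to genes through loops
#'
#' Emits one SGL per (SNP, gene, loop) triple where the SNP falls in one
#' anchor and the gene's TSS in the opposing anchor (both orientations).
#' Every SNP is crossed with every TSS (pairtobed semantics). Output is
#' deduplicated on (rsid, gene_id, loop coordinates, resolution, sample).
#'
#' @param loops Loop tibble.
#' @param snps SNP tibble (`rsid, chrom, pos` 1-based, optional
#'   `posterior_prob, study_id, disease`).
#' @param tss TSS tibble from [tss_from_genes()].
#' @return An SGL tibble; one row per link.
#' @export
find_gwas_sgls <- function(loops, snps, tss) {
  if (nrow(loops) == 0 || nrow(snps) == 0 || nrow(tss) == 0)
    return(sgl_row_template())
  snp_hits <- pair_feature_overlap(loops, snp_intervals(snps))
  tss_hits <- pair_feature_overlap(loops, tss)
  link <- function(snp_side, tss_side) {
    s <- filter(snp_hits, .data$anchor == snp_side)
    t <- filter(tss_hits, .data$anchor == tss_side)
    j <- dplyr::inner_join(select(s, "loop_index", snp_idx = "feature_index"),
                           select(t, "loop_index", tss_idx = "feature_index"),
                           by = "loop_index", relationship = "many-to-many")
    sgl_from_indices(loops, snps, tss, j$snp_idx, j$tss_idx, j$loop_index,
                     snp_side)
  }
  out <- bind_rows(link("A", "B"), link("B", "A"))
  distinct(out, .data$rsid, .data$gene_id, .data$chrom, .data$start1,
           .data$start2, .data$resolution, .data$sample_id,
           .keep_all = TRUE) |>
    arrange(.data$chrom, .data$start1, .data$start2, .data$rsid,
            .data$gene_id)
}

#' Map eQTL SNP-gene pairs through loops
#'
#' Unlike GWAS mapping, only the eQTL's own paired gene counts: a loop is an
#' SGL iff one anchor contains the eQTL SNP and the opposing anchor contains
#' the TSS of its paired gene (pairtopair semantics).
#'
#' @param loops Loop tibble.
#' @param eqtls eQTL tibble (`rsid, chrom, pos, gene_id`, optional
#'   `study_id`).
#' @param tss TSS tibble from [tss_from_genes()].
#' @return An SGL tibble.
#' @export
find_eqtl_sgls <- function(loops, eqtls, tss) {
  if (nrow(loops) == 0 || nrow(eqtls) == 0) return(sgl_row_template())
  known <- eqtls$gene_id %in% tss$gene_id
  if (any(!known)) {
    warn(paste0("skipped ", sum(!known), " eQTL record(s) with gene_id ",
                "absent from the TSS table"))
    eqtls <- eqtls[known, , drop = FALSE]
  }
  if (nrow(eqtls) == 0) return(sgl_row_template())
  ti <- match(eqtls$gene_id, tss$gene_id)
  pairs <- tibble(chrom1 = eqtls$chrom, start1 = eqtls$pos - 1,
                  end1 = eqtls$pos,
                  chrom2 = tss$chrom[ti], start2 = tss$start[ti],
                  end2 = tss$end[ti])
  # reuse the per-anchor machinery to keep track of which anchor holds the SNP
  snp_hits <- pair_feature_overlap(
    loops, select(pairs, chrom = "chrom1", start = "start1", end = "end1"))
  tss_hits <- pair_feature_overlap(
    loops, select(pairs, chrom = "chrom2", start = "start2", end = "end2"))
  link <- function(snp_side, tss_side) {
    s <- filter(snp_hits, .data$anchor == snp_side)
    t <- filter(tss_hits, .data$anchor == tss_side)
    dplyr::inner_join(select(s, "loop_index", pair_idx = "feature_index"),
                      select(t, "loop_index", tss_pair = "feature_index"),
                      by = "loop_index", relationship = "many-to-many") |>
      filter(.data$pair_idx == .data$tss_pair) |>
      mutate(snp_anchor = snp_side)
  }
  j <- bind_rows(link("A", "B"), link("B", "A"))
  if (nrow(j) == 0) return(sgl_row_template())
  snps_like <- eqtls
  if (!"disease" %in% names(snps_like)) snps_like$disease <- NA_character_
  out <- sgl_from_indices(loops, snps_like, tss[ti, , drop = FALSE],
                          j$pair_idx, j$pair_idx, j$loop_index, j$snp_anchor)
  distinct(out, .data$rsid, .data$gene_id, .data$chrom, .data$start1,
           .data$start2, .data$resolution, .data$sample_id,
           .keep_all = TRUE) |>
    arrange(.data$chrom, .data$start1, .data$start2, .data$rsid,
            .data$gene_id)
}

#' Summarize SGL multiplicity
#'
#' Counts links, distinct links (pooled across samples on the key
#' rsid/gene/loop-coordinates/resolution), distinct SNPs, genes and loops,
#' and the per-SNP / per-gene link-count distributions with their medians
#' and singleton fractions.
#'
#' @param sgls SGL tibble from [find_gwas_sgls()] or [find_eqtl_sgls()].
#' @return A list: scalar counts (`n_sgls, n_unique_sgls, n_snps, n_genes,
#'   n_loops`), tibbles `per_snp` (`rsid, n_genes`) and `per_gene`
#'   (`gene_id, n_snps`), medians `median_genes_per_snp`,
#'   `median_snps_per_gene`, and singleton fractions
#'   `singleton_frac_snps`, `singleton_frac_genes`.
#' @export
sgl_summary <- function(sgls) {
  if (nrow(sgls) == 0) {
    return(list(n_sgls = 0L, n_unique_sgls = 0L, n_snps = 0L, n_genes = 0L,
                n_loops = 0L,
                per_snp = tibble(rsid = character(), n_genes = integer()),
                per_gene = tibble(gene_id = character(), n_snps = integer()),
                median_genes_per_snp = NA_real_,
                median_snps_per_gene = NA_real_,
                singleton_frac_snps = NA_real_,
                singleton_frac_genes = NA_real_))
  }
  uniq <- distinct(sgls, .data$rsid, .data$gene_id, .data$chrom,
                   .data$start1, .data$start2, .data$resolution)
  per_snp <- sgls |>
    distinct(.data$rsid, .data$gene_id) |>
    count(.data$rsid, name = "n_genes")
  per_gene <- sgls |>
    distinct(.data$rsid, .data$gene_id) |>
    count(.data$gene_id, name = "n_snps")
  list(
    n_sgls = nrow(sgls),
    n_unique_sgls = nrow(uniq),
    n_snps = dplyr::n_distinct(sgls$rsid),
    n_genes = dplyr::n_distinct(sgls$gene_id),
    n_loops = nrow(distinct(sgls, .data$chrom, .data$start1, .data$start2,
                            .data$resolution)),
    per_snp = per_snp,
    per_gene = per_gene,
    median_genes_per_snp = median(per_snp$n_genes),
    median_snps_per_gene = median(per_gene$n_snps),
    singleton_frac_snps = mean(per_snp$n_genes == 1),
    singleton_frac_genes = mean(per_gene$n_snps == 1))
}

#' Nearby-gene null link counts
#'
#' Links each SNP to every gene whose body overlaps the window
#' `[pos - window, pos + window]` (closed on both sides, 1-based), the null
#' that SGL mapping is compared against.
#'
#' @param snps SNP tibble (`rsid, chrom, pos` 1-based).
#' @param genes Gene tibble (0-based half-open bodies).
#' @param window Half-width in bp (default 1 Mb).
#' @return A list of tibbles `genes_per_snp` (`rsid, n`) and
#'   `snps_per_gene` (`gene_id, n`), both including zero counts.
#' @export
nearby_gene_null <- function(snps, genes, window = 1e6) {
  if (window <= 0) abort("window must be > 0")
  win <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = pmax(1, snps$pos - window),
                              end = snps$pos + window))
  gg <- as_granges0(genes)
  hits <- find_overlaps_quiet(win, gg)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  n_per_snp <- tabulate(qh, nbins = nrow(snps))
  n_per_gene <- tabulate(sh, nbins = nrow(genes))
  list(genes_per_snp = tibble(rsid = snps$rsid, n = n_per_snp),
       snps_per_gene = tibble(gene_id = genes$gene_id, n = n_per_gene))
}

#' Specificity test of SGL link counts against a null
#'
#' One-sided Mann-Whitney U test with alternative "SGL counts are
#' stochastically smaller than the null counts" (i.e. SGL linking is more
#' specific), using the normal approximation with tie correction.
#'
#' @param sgl_counts Numeric vector of per-entity SGL link counts.
#' @param null_counts Numeric vector of per-entity null link counts.
#' @return A one-row tibble `(statistic, p_value, method, degenerate)`;
#'   `degenerate` is `TRUE` when both samples are a single shared constant
#'   (p fixed at 0.5).
#' @export
specificity_test <- function(sgl_counts, null_counts) {
  if (!length(sgl_counts) || !length(null_counts))
    abort("both count distributions must be non-empty")
  if (length(unique(c(sgl_counts, null_counts))) == 1L) {
    warn("degenerate: all counts identical; p fixed at 0.5")
    return(tibble(statistic = NA_real_, p_value = 0.5,
                  method = "Mann-Whitney (less)", degenerate = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(sgl_counts, null_counts,
                                     alternative = "less", exact = FALSE,
                                     correct = TRUE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         method = "Mann-Whitney (less)", degenerate = FALSE)
}
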