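test_that("TSS placement is strand-conditional with width 1", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), gene_name = c("G1", "G2"),
                          chrom = "chr1", start = 1000, end = 5000,
                          strand = c("+", "-"))
  tss <- tss_from_genes(genes)
  expect_equal(tss$start, c(1000, 4999))
  expect_equal(tss$end - tss$start, c(1, 1))
  set.seed(8)
  mixed <- tibble::tibble(gene_id = paste0("g", 1:50),
                          gene_name = paste0("G", 1:50), chrom = "chr1",
                          start = sample.int(1e6, 50))
  mixed$end <- mixed$start + sample.int(1e5, 50)
  mixed$strand <- sample(c("+", "-"), 50, replace = TRUE)
  tss2 <- tss_from_genes(mixed)
  oracle <- ifelse(mixed$strand == "+", mixed$start, mixed$end - 1)
  expect_equal(tss2$start, oracle)
})

test_that("GWAS SGLs require SNP and TSS on opposing anchors", {
  loops <- tibble::tibble(chrom1 = "chr1", start1 = 10000, end1 = 15000,
                          chrom2 = "chr1", start2 = 40000, end2 = 45000,
                          q_value = 1e-4, resolution = 5000, sample_id = "s")
  snps <- tibble::tibble(rsid = "rs1", chrom = "chr1", pos = 12000,
                         posterior_prob = 0.9, study_id = "st",
                         disease = "d")
  tss_opp <- tss_from_genes(tibble::tibble(
    gene_id = "g1", gene_name = "G1", chrom = "chr1", start = 42000,
    end = 43000, strand = "+"))
  tss_same <- tss_from_genes(tibble::tibble(
    gene_id = "g2", gene_name = "G2", chrom = "chr1", start = 13000,
    end = 14000, strand = "+"))
  expect_equal(nrow(find_gwas_sgls(loops, snps, tss_opp)), 1L)
  expect_equal(nrow(find_gwas_sgls(loops, snps, tss_same)), 0L)
})

test_that("planted SGL scenarios are recovered exactly, dedup idempotent", {
  for (k in c(0L, 1L, 25L)) {
    sc <- synth_sgl_scenario(planted = k, seed = 20 + k)
    sgls <- find_gwas_sgls(sc$loops, sc$snps, tss_from_genes(sc$genes))
    expect_equal(nrow(sgls), k)
    expect_setequal(sgls$rsid, sc$truth$rsid)
    # dedup idempotence: mapping an already-deduplicated set changes nothing
    expect_equal(find_gwas_sgls(sc$loops, sc$snps,
                                tss_from_genes(sc$genes)), sgls)
  }
})

test_that("GWAS SGL mapping equals brute-force triple enumeration", {
  set.seed(31)
  loops <- random_loop_tbl(40, chroms = "c1")
  snps <- tibble::tibble(rsid = paste0("rs", 1:30), chrom = "c1",
                         pos = sample.int(60000, 30))
  genes <- tibble::tibble(gene_id = paste0("g", 1:30),
                          gene_name = paste0("G", 1:30), chrom = "c1",
                          start = sample.int(60000, 30))
  genes$end <- genes$start + 500
  genes$strand <- sample(c("+", "-"), 30, replace = TRUE)
  tss <- tss_from_genes(genes)
  got <- find_gwas_sgls(loops, snps, tss)
  inside <- function(p0, s, e) p0 >= s && p0 < e  # 0-based point
  brute_keys <- character(0)
  for (i in seq_len(nrow(loops))) {
    for (s in seq_len(nrow(snps))) {
      for (g in seq_len(nrow(tss))) {
        sA <- inside(snps$pos[s] - 1, loops$start1[i], loops$end1[i])
        sB <- inside(snps$pos[s] - 1, loops$start2[i], loops$end2[i])
        tA <- inside(tss$start[g], loops$start1[i], loops$end1[i])
        tB <- inside(tss$start[g], loops$start2[i], loops$end2[i])
        if ((sA && tB) || (sB && tA))
          brute_keys <- c(brute_keys, paste(
            snps$rsid[s], tss$gene_id[g], loops$chrom1[i],
            loops$start1[i], loops$start2[i]))
      }
    }
  }
  got_keys <- paste(got$rsid, got$gene_id, got$chrom, got$start1,
                    got$start2)
  expect_setequal(got_keys, unique(brute_keys))
  expect_equal(nrow(got), length(unique(brute_keys)))
})

test_that("eQTL SGLs preserve the SNP-gene pairing", {
  loops <- tibble::tibble(chrom1 = "chr1", start1 = 10000, end1 = 15000,
                          chrom2 = "chr1", start2 = 40000, end2 = 45000,
                          q_value = 1e-4, resolution = 5000, sample_id = "s")
  genes <- tibble::tibble(gene_id = c("gX", "gY"),
                          gene_name = c("GX", "GY"), chrom = "chr1",
                          start = c(42000, 43000), end = c(42500, 43500),
                          strand = "+")
  tss <- tss_from_genes(genes)
  own <- tibble::tibble(rsid = "rs1", chrom = "chr1", pos = 12000,
                        gene_id = "gX")
  other <- tibble::tibble(rsid = "rs1", chrom = "chr1", pos = 12000,
                          gene_id = "gY")
  expect_equal(find_eqtl_sgls(loops, own, tss)$gene_id, "gX")
  # pairing preserved: rs1->gY matches because gY TSS is also in anchor B,
  # but rs1 paired with a gene whose TSS is in the SAME anchor must not
  same_anchor_gene <- tibble::tibble(
    gene_id = "gZ", gene_name = "GZ", chrom = "chr1", start = 13000,
    end = 13500, strand = "+")
  tss2 <- tss_from_genes(dplyr::bind_rows(genes, same_anchor_gene))
  bad <- tibble::tibble(rsid = "rs1", chrom = "chr1", pos = 12000,
                        gene_id = "gZ")
  expect_equal(nrow(find_eqtl_sgls(loops, bad, tss2)), 0L)
  expect_warning(res <- find_eqtl_sgls(
    loops, tibble::tibble(rsid = "rs1", chrom = "chr1", pos = 12000,
                          gene_id = "gMissing"), tss), "absent")
  expect_equal(nrow(res), 0L)
})

test_that("multiplicity summary reflects planted link structure", {
  sc <- synth_sgl_scenario(planted = 10, seed = 77)
  sgls <- find_gwas_sgls(sc$loops, sc$snps, tss_from_genes(sc$genes))
  s <- sgl_summary(sgls)
  # planted links are 1:1 snp-gene pairs
  expect_equal(s$median_genes_per_snp, 1)
  expect_equal(s$singleton_frac_genes, 1)
  expect_equal(s$n_unique_sgls, 10)
  # planted one-to-many: gene g linked to 5 SNPs
  many <- dplyr::bind_rows(lapply(1:5, function(i)
    dplyr::mutate(sgls[1, ], rsid = paste0("rsM", i), gene_id = "gM")))
  s2 <- sgl_summary(many)
  expect_equal(s2$per_gene$n_snps, 5)
  expect_equal(s2$singleton_frac_genes, 0)
  s0 <- sgl_summary(sgls[0, ])
  expect_equal(s0$n_sgls, 0L)
  expect_equal(nrow(s0$per_snp), 0L)
})

test_that("nearby-gene null uses a closed 1 Mb window with body overlap", {
  snps <- tibble::tibble(rsid = "rs1", chrom = "c1", pos = 5e6)
  genes <- tibble::tibble(
    gene_id = c("in1", "in2", "in3", "edge", "out"),
    gene_name = c("in1", "in2", "in3", "edge", "out"), chrom = "c1",
    start = c(4.2e6, 4.9e6, 5.5e6, 6e6 - 1, 6.5e6),
    end = c(4.3e6, 5.1e6, 5.6e6, 6e6 + 5e4, 6.6e6), strand = "+")
  nul <- nearby_gene_null(snps, genes, window = 1e6)
  expect_equal(nul$genes_per_snp$n, 4)  # edge gene at pos+window included
  expect_equal(nul$snps_per_gene$n, c(1, 1, 1, 1, 0))
  set.seed(99)
  rs <- tibble::tibble(rsid = paste0("r", 1:20), chrom = "c1",
                       pos = sample.int(1e7, 20))
  gs <- tibble::tibble(gene_id = paste0("g", 1:40),
                       gene_name = paste0("g", 1:40), chrom = "c1",
                       start = sample.int(1e7, 40))
  gs$end <- gs$start + sample.int(2e5, 40)
  gs$strand <- "+"
  nul2 <- nearby_gene_null(rs, gs, window = 1e6)
  oracle <- vapply(seq_len(20), function(i) {
    sum(gs$start + 1 <= rs$pos[i] + 1e6 & gs$end >= rs$pos[i] - 1e6)
  }, integer(1))
  expect_equal(nul2$genes_per_snp$n, oracle)
})

test_that("specificity test is left-sided with tie-corrected approximation", {
  p_sep <- specificity_test(rep(1, 50), rep(10, 50))$p_value
  expect_lt(p_sep, 1e-6)
  p_rev <- specificity_test(rep(10, 50), rep(1, 50))$p_value
  expect_gt(p_rev, 0.99)
  expect_warning(deg <- specificity_test(rep(3, 10), rep(3, 10)),
                 "degenerate")
  expect_equal(deg$p_value, 0.5)
  expect_error(specificity_test(numeric(0), 1:3), "non-empty")
})
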