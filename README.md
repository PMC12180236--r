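# loopkit

Downstream analysis of HiChIP chromatin loops in R.

HiChIP couples proximity ligation with chromatin immunoprecipitation and
yields *loops*: pairs of genomic anchors (typically 5-25 kb bins) in
significant 3D contact, each with a loop-caller q-value. Once loops are
called, a series of bespoke downstream computations turns them into
biology, and those computations are what this package provides, as
tidyverse-style functions over plain tables:

* **Genomic plumbing** — readers/writers for BEDPE loops (FitHiChIP,
  HiCCUPS and plain dialects), narrowPeak, BED, chrom.sizes and SNP /
  gene / eQTL tables; `pairtobed`/`pairtopair`-style interval and
  anchor-pair intersection with slack; peak recall.
* **Quality control** — per-metric 0-10 scores by piecewise-affine
  normalization onto Poor/Warning/Good bands (boundaries at scores
  6 and 8), stage aggregation, worst-of final flags, and
  high-confidence sample selection (flag Good/Warning and > 10,000
  stringent 5 kb loops for H3K27ac sets, > 2,000 for CTCF).
* **Replicate reproducibility** — the stratum-adjusted correlation
  coefficient (SCC): per-diagonal Pearson correlations of mean-filter
  smoothed contact matrices, combined with weights
  `N_d * sigma_a,d * sigma_b,d`; replicates merge only when all pairwise
  SCCs exceed 0.8.
* **SNP-to-gene links (SGLs)** — a loop links a variant to a gene when
  the SNP occupies one anchor and the gene's TSS the opposing anchor.
  GWAS mode crosses SNPs with all TSSs; eQTL mode preserves the SNP-gene
  pairing. A nearby-gene null (±1 Mb) plus a left-sided Mann-Whitney
  test quantifies how much more specific loop-based linking is.
* **Motif pairs at anchors** — conserved anchors (≥ ⌈0.8 n⌉ samples),
  GC-quantile-matched background sampling, representative-peak motif
  annotation, and a block-bootstrap enrichment test that redraws each loop's
  anchors uniformly within their chromosome and recounts motif pairs;
  BH correction over pairs within the top-50 motifs.
* **Regulatory networks** — anchors as promoter/enhancer/other nodes,
  edges weighted by `-log10(q)` capped at 20 and scaled to [0,1],
  two-level Louvain communities per chromosome, and a connectivity-based
  (density + conductance + strength, Borda-aggregated) community
  ranking.
* **2D embeddings and APA** — log10/reciprocal contact transforms,
  deterministic Kamada-Kawai layouts, bounded Voronoi spatial weights,
  global and local Moran's I with permutation inference and HH/HL/LH/LL
  quadrants, and aggregate peak analysis (center over the 15-30 kb
  distal corner, and center over all non-center pixels).
* **Synthetic data** — seeded generators for every input type with
  planted structure (loops with distance decay, planted SGL triples,
  planted motif pairs, contact windows with center enrichment and
  autocorrelated signals), so the entire pipeline is testable offline.

## Worked example

Plant 25 SNP-gene-loop triples in a synthetic genome, recover them, and
test specificity against the nearby-gene null:

```r
library(loopkit)

sc   <- synth_sgl_scenario(n_loops = 120, planted = 25, seed = 7)
tss  <- tss_from_genes(sc$genes)
sgls <- find_gwas_sgls(sc$loops, sc$snps, tss)
dplyr::select(sgls, rsid, gene_id, chrom, start1, start2, q_value)
#> # A tibble: 25 × 6
#>   rsid  gene_id chrom  start1  start2  q_value
#>   <chr> <chr>   <chr>   <dbl>   <dbl>    <dbl>
#> 1 rsP16 GP16    chrS1  435000  700000 1.02e-12
#> 2 rsP17 GP17    chrS1 1385000 1730000 2.37e-12
#> 3 rsP20 GP20    chrS1 4195000 4665000 6.73e- 6
#> 4 rsP21 GP21    chrS1 4275000 4435000 1.46e- 8
#> # i 21 more rows
```

All 25 planted links are recovered: each row is a loop whose one anchor
holds the SNP and whose opposing anchor holds the gene's TSS. Loop-based
linking is far more specific than linking every gene within 1 Mb:

```r
s   <- sgl_summary(sgls)
nul <- nearby_gene_null(sc$snps, sc$genes, window = 1e6)
specificity_test(s$per_snp$n_genes, nul$genes_per_snp$n)
#> # A tibble: 1 × 4
#>   statistic  p_value method              degenerate
#>       <dbl>    <dbl> <chr>               <lgl>
#> 1         0 9.20e-14 Mann-Whitney (less) FALSE
```

The per-SNP link counts (median 1 gene per SNP here) are stochastically
smaller than the nearby-gene counts — the left-sided Mann-Whitney p-value
is ~1e-13.

A contact window with loop pixels planted at 3x enrichment, analyzed by
APA and by Moran's I on its 2D embedding:

```r
w <- synth_contact_window(seed = 7, enrichment = 3)
apa(w$mat, w$loop_bins, resolution = w$resolution)
#> APA: score = 2.836, ratio = 2.941 (30 loops used, 0 skipped)

emb <- layout_kk(transform_contacts(w$mat, "hichip"))
moran_analysis(emb, w$signal, n_perm = 999, seed = 7)
#> Global Moran's I = 0.4309 (E[I] = -0.0050, p = 0.001, 999 perms)
#> local: 200 bins, 47 significant at p <= 0.05
```

The APA score recovers the planted enrichment to within a few percent
(the distal-corner normalization is slightly conservative under distance
decay), and the planted high-signal block produces strong positive
spatial autocorrelation in the embedding.

`autoplot()` methods exist for embeddings, Moran results and APA
matrices; `tidy()`/`glance()` methods for Moran, SCC, APA and community
objects. A thin command-line wrapper (`inst/exec/loopkit`) exposes the
same functions as subcommands (`synth`, `convert`, `overlap`, `qc`,
`sgl`, `motifs`, `network`, `embed2d`, `apa`), each run writing a
`manifest.json` with seeds and input digests.

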