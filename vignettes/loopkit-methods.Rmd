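---
title: "Methods: downstream analysis of HiChIP loops with loopkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream analysis of HiChIP loops with loopkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopkit)
```

# Scope

loopkit implements the downstream computations that turn HiChIP loop calls
into biological results: sample quality control, replicate reproducibility,
SNP-to-gene linking, motif-pair enrichment at loop anchors, regulatory
network communities, and 2D chromatin embeddings with spatial statistics.
Upstream processing — read alignment, peak calling, loop calling, motif
scanning — is out of scope: their outputs (BEDPE, narrowPeak, FIMO-style
occurrence tables) are loopkit's inputs. All functions take data frames and
return tibbles; every stochastic step takes an explicit seed.

Coordinates are 0-based half-open throughout (BED convention). SNP
positions, which arrive 1-based, are stored as-is and shifted to width-1
intervals `[pos-1, pos)` inside overlap operations. Overlap always means at
least one shared base pair, the bedtools default, because every rule
implemented here was originally expressed through bedtools semantics.
Inter-chromosomal loop records are rejected at parse time: peak-anchored
HiChIP loop callers emit cis contacts only (spans of roughly 20 kb-2 Mb),
so a trans record indicates a malformed file.

# Quality-control scoring

Each quality metric (mapping rate, valid-pair percentages, peak and loop
counts, ChIP library-complexity measures such as NRF/PBC1/PBC2/NSC/RSC) is
mapped onto a 0-10 score using three intervals bounded by thresholds $t_1$
and $t_2$: raw values in $[\min, t_1]$ map affinely onto $[0, 6]$ (Poor),
$[t_1, t_2]$ onto $[6, 8]$ (Warning) and $[t_2, \mathrm{upper}]$ onto
$[8, 10]$ (Good). Bounded metrics (percentages, fractions) use their
natural maximum as the upper bound; unbounded metrics resolve it from the
cohort as $Q_3 + 1.5\,\mathrm{IQR}$, so upper outliers score 10. For
metrics where larger is worse (duplicate rates) the complement $10 -
\mathrm{score}$ is used, which flips the monotonicity but preserves the
band geometry. We implement the piecewise-affine interpolation (interval
endpoints map to 0/6/8/10 exactly) rather than a slope-only rescaling: the
band definitions are explicit about where the boundaries must land, and a
pure slope formula only reproduces them when the metric minimum is zero.

Stage scores are plain means of the member metric scores, flagged Poor
($S < 6$), Warning ($6 \le S < 8$, left-closed) or Good ($S \ge 8$). The
final per-configuration flag is Good only when every stage is Good;
otherwise it is the worst stage flag. The complete table of mixed-flag
combinations used in the original QC design is not public, so worst-of is
the documented stand-in — it is conservative (never upgrades a sample) and
reduces to the published rule on the all-Good case. Default thresholds
ship in `inst/extdata/qc_metric_specs.yaml` and are deliberately
overridable: they encode field-standard expectations (e.g. ENCODE
library-complexity cutoffs), not universal truths.

High-confidence sample sets keep Good/Warning samples whose stringent 5 kb
loop count strictly exceeds 10,000 (H3K27ac regulatory sets) or 2,000
(CTCF structural sets).

# Replicate reproducibility (SCC)

Two binned contact matrices are compared with a stratum-adjusted
correlation coefficient: both matrices are smoothed with a
$(2h+1)\times(2h+1)$ mean filter, a Pearson correlation $r_d$ is computed
inside each diagonal stratum $d$ (pairs of bins at fixed genomic
distance), and strata are combined as

$$\mathrm{SCC} = \frac{\sum_d N_d \sigma_{a,d} \sigma_{b,d}\, r_d}
                      {\sum_d N_d \sigma_{a,d} \sigma_{b,d}},$$

the HiCRep weighting, which emphasizes strata that carry signal in both
replicates. Strata with zero variance in either matrix carry no
correlation information and are skipped (and counted). The smoothing
half-width $h$ is an input; `scc_train()` offers a small grid search that
stops when the SCC gain per increment of $h$ flattens, mirroring how a
smoothing level is usually trained on replicate pairs, but the merge rule
itself never requires it. A replicate group is merged only when **every**
pairwise SCC strictly exceeds 0.8; a single replicate merges vacuously
(with a warning), and a missing pair is an error rather than a silent
pass.

# SNP-to-gene links

A loop becomes an SGL when one anchor contains a variant and the opposing
anchor contains a gene's transcription start site. TSSs are width-1
intervals: the gene start on the plus strand, the gene end on the minus
strand. Two mapping modes implement a deliberate asymmetry:

* **GWAS mode** crosses every fine-mapped SNP with every TSS
  (`pairtobed` semantics): the question is which genes a risk variant
  could regulate through any loop.
* **eQTL mode** preserves the SNP-gene pairing of the input
  (`pairtopair` semantics): an eQTL's loop support only counts toward its
  own target gene.

Links are deduplicated on (rsid, gene, loop coordinates, resolution,
sample); the pooled distinct-link count drops the sample key. Multiplicity
summaries report per-SNP distinct-gene counts and per-gene distinct-SNP
counts, their medians, and singleton fractions.

Specificity is assessed against a nearby-gene null that links each SNP to
every gene whose body overlaps a ±1 Mb window (closed at both boundaries —
a gene starting exactly at `pos + window` is still "within 1 Mb"). A
left-sided Mann-Whitney test (normal approximation with tie correction;
ties are unavoidable in small count data) asks whether SGL link counts are
stochastically smaller, i.e. more specific, than the null's. When both
samples are a single shared constant the statistic is undefined and the
test reports p = 0.5 with a warning instead of NaN.

# Motif pairs at loop anchors

**Conserved anchors.** Pooling the unique 5 kb anchors of all samples in a
set, an anchor is conserved when it loops in at least
$\lceil 0.8\,n \rceil$ of $n$ samples — 44/54, 22/27 and 9/11 at the
published set sizes. The non-conserved complement is retained as the
natural background universe.

**GC-matched background.** For sequence-based enrichment a background is
drawn from the non-conserved anchors so that its GC distribution matches
the conserved foreground: pool sequences are assigned to 0.5% GC
quantile bins, and each foreground sequence draws one pool sequence from
its bin. Draws are with replacement across foreground sequences because a
bin may hold fewer pool members than foreground queries; an empty bin
falls back to the nearest non-empty bin with a warning. The actual
sequence-level enrichment scan is delegated to external tools
(`export_enrichment_inputs()` writes the FASTA/BED pair); loopkit consumes
the scanner's occurrence table.

**Anchor annotation.** Each anchor is represented by the overlapping
ChIP-seq peak with the highest signal value (ties broken by leftmost
start); the representative peak set is deduplicated since one peak can
represent several anchors. A motif is assigned to an anchor when an
occurrence overlaps both the anchor and its representative peak; anchors
without a representative peak get the empty set.

**Block bootstrap.** Loops touching blacklisted regions are removed first.
A loop exhibits the unordered pair $\{a, b\}$ (self-pairs allowed) when
$a$ annotates one anchor and $b$ the other; each loop contributes at most
once per pair. The null preserves the genomic block structure: in each
simulation every loop's two anchors are replaced by anchors drawn
uniformly **with replacement from the same chromosome's anchor pool**,
annotations traveling with the anchors, and pairs are recounted. This
holds per-chromosome loop counts and the per-chromosome annotation
multiset fixed while destroying anchor-anchor coupling. The default
p-value is the add-one estimator $(1 + \#\{\mathrm{sim} \ge
\mathrm{obs}\})/(1 + n_{\mathrm{sim}})$, which cannot be exactly zero and
is the statistically safer summary of a finite simulation; the plain
fraction used by the original analysis is available via
`add_one = FALSE`. Note the interaction with multiple testing: at
$n_{\mathrm{sim}}$ simulations and $m$ retained pairs the add-one
estimator bounds every BH-adjusted p below by $m/(n_{\mathrm{sim}}+1)$,
so detecting adjusted significance at small simulation counts requires
either the plain estimator or more simulations (the production default is
100,000).

Pairs are then restricted to those whose **both** members are among the
sample's top-k motifs (default 50), ranking motifs by how often they
appear across the sample's observed pairs with alphabetical tie-breaks,
and Benjamini-Hochberg adjustment is applied to the retained p-values
only. Cross-sample summaries report, per pair, the proportion of samples
where it is significant among samples where it was tested.

# Loop networks and communities

Anchors become nodes; loops become undirected edges weighted by
$-\log_{10}(q)$, capped at 20 and divided by 20, so weights live in
$[0, 1]$ and saturate for astronomically significant loops. Nodes are
labeled promoter when a TSS lies within ±2.5 kb of the anchor (expanding
the anchor or the TSS is equivalent under half-open overlap; we expand the
anchor), else enhancer when a ChIP-seq peak overlaps with no slack, else
"other"; promoter takes priority.

Louvain modularity maximization runs per chromosome (high level), then
again inside each high-level community (subcommunities). The sweep order
is seeded for reproducibility. Community prioritization does not
reproduce the original black-box ranking tool; instead a documented
surrogate aggregates three connectivity properties — internal edge
density, conductance (boundary leakage, lower is better) and weighted
internal strength — by Borda rank aggregation within each level, and tags
every output row with `method = "borda_surrogate"` so downstream users
can tell the scores' provenance.

# 2D embeddings, Moran's I, APA

For a gene-centric contact window, counts are $\log_{10}$-transformed,
entries below the assay threshold (0.1 for HiChIP, 1 for Hi-C — HiChIP's
targeted enrichment makes small normalized counts meaningful earlier) are
zeroed, and distances are reciprocals of the surviving values. The
Kamada-Kawai layout embeds the resulting weighted graph in 2D; nodes are
initialized on a circle in genomic order, which makes the layout fully
deterministic. Bins outside the largest connected component cannot be
embedded and are dropped with a report.

Spatial weights come from a Voronoi tessellation of the embedded points,
bounded by the coordinate bounding box padded by 10% of its range so
boundary cells are finite: $w_{ij} = 1$ when cells share an edge
(computed exactly by clipping each pair's perpendicular bisector against
all other sites' half-planes), then rows are standardized. Degenerate
configurations (duplicates, collinearity) receive a small deterministic
jitter with a warning.

Global Moran's I quantifies whether the overlaid 1D signal clusters in
the embedding; inference is by permutation (default 999), one-sided for
clustering, with the add-one p. Local Moran's I uses conditional
permutation per bin (own value fixed, neighbors resampled from the
remaining bins) and reports the more extreme tail, matching the
convention of standard exploratory spatial data analysis software;
quadrants HH/HL/LH/LL combine the sign of the centered signal with the
sign of its spatial lag. Under row-standardized weights the mean of the
local statistics equals the global statistic, which the tests verify to
1e-9.

Aggregate peak analysis averages contact submatrices centered on loop
pixels. With the matrix oriented so rows follow the upstream anchor, the
APA score divides the center pixel by the mean of the corner block 15-30
kb downstream of the upstream locus and 15-30 kb upstream of the
downstream locus (offsets 3..6 bins at 5 kb — the corner closer to the
diagonal, making the score conservative against distance decay); the APA
ratio divides the center by the mean of all non-center pixels. Loops
whose window leaves the matrix are skipped and counted.

# Synthetic data

All stages are exercised without downloads by seeded generators whose
defaults encode the study conditions rather than tunable dials:

* `synth_loops()`: anchors on a 5 kb grid over a two-chromosome 10 Mb
  genome (large enough for distance strata, small enough for seconds-scale
  tests), spans sampled $\propto d^{-\alpha}$ truncated to 20 kb-2 Mb (the
  loop caller's distance window), q-values from a significant/background
  mixture.
* `synth_sgl_scenario()`: pairwise-disjoint anchors guarantee that exactly
  the planted (SNP, gene, loop) triples satisfy the opposing-anchor rule;
  distractors include same-anchor SNP+TSS pairs (rule violators) and
  entities outside all anchors.
* `synth_motif_scenario()`: independent per-anchor motif presence
  (probability 0.15, 20 motifs) is an exact null for the block bootstrap;
  planted pairs are forced onto opposing anchors of extra loops at
  $(m-1) \times 2f^2 n$ copies, targeting $m$ times the independence
  expectation.
* `synth_contact_window()`: Poisson counts around a $\propto
  (|i-j|+1)^{-\alpha}$ decay with planted loop pixels multiplied by the
  enrichment, plus a 1D signal with a planted contiguous high block on a
  smoothed noise floor. The default decay is shallow
  ($\alpha = 0.3$) and planted pixels sit at separations of at least a
  third of the window, where the decay background varies by only a few
  percent across an APA window — by construction, the planted enrichment
  is then identifiable to within ~10%; with steep decay at short
  separations the conservative corner normalization would absorb part of
  it.

What the generators do **not** emulate: coverage biases and mappability
structure, karyotype abnormalities, correlated q-values along the genome,
TAD-scale block structure in contact matrices, and realistic motif
co-occurrence hierarchies. Passing the planted-recovery and calibration
tests therefore demonstrates algorithmic correctness and statistical
calibration under clean conditions, not robustness to every artifact of
real HiChIP data.

# Numerical and design notes

* Problem sizes in the test-suite and acceptance runs are chosen for
  seconds-to-minutes runtimes: 400×400 matrices for SCC nulls, 2,000
  bootstrap simulations (production default 100,000), 999 Moran
  permutations, 120-300 synthetic loops per scenario.
* Tie-breaks are deterministic everywhere: representative peaks by
  signal then leftmost start; motif top-k ranking alphabetical within
  frequency; Louvain seeded.
* The Mann-Whitney degenerate case (all counts identical) returns p = 0.5
  with a warning; empty truth sets make recall an error rather than NaN;
  all-zero contact windows are an error since no graph exists.
* `loopkit_run()` (and the `inst/exec/loopkit` script) is a thin
  dispatcher over these functions; each run writes a `manifest.json`
  (command, flags, seed, input MD5 digests, package version, timestamp).
  Outputs are computed before any file is written, so failed runs leave
  no partial outputs.

# Limitations

* Likelihood-based community prioritization (CRank and relatives) is
  approximated by the Borda surrogate; rankings agree on clear-cut cases
  (dense vs sparse communities) but are not numerically comparable to
  scores from those tools.
* The exact mixed-flag QC combination table is not public; worst-of is a
  conservative stand-in.
* Voronoi adjacency depends on how boundary cells are bounded; the padded
  bounding box (10%) is one reasonable choice and slightly affects
  neighbor structure for hull points.
* GC matching operates on user-supplied sequences; loopkit does not
  extract sequence from a genome FASTA itself.
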