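Package: loopkit
Title: Downstream Analysis of HiChIP Chromatin Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for downstream analysis of HiChIP
    chromatin loop calls. Provides readers for BEDPE loop files, narrowPeak
    peaks and SNP/gene/eQTL tables; interval and anchor-pair intersection
    with slack; per-metric quality-control scoring with Poor/Warning/Good
    flags; stratum-adjusted correlation coefficients (SCC) for replicate
    reproducibility and merge decisions; SNP-to-gene link (SGL) mapping for
    fine-mapped GWAS variants and eQTLs with a nearby-gene null comparison;
    conserved-anchor identification, GC-matched background construction and
    a block-bootstrap motif-pair enrichment test; regulatory loop networks
    with two-level Louvain communities and connectivity-based ranking;
    2D chromatin embeddings via Kamada-Kawai layout with Voronoi spatial
    weights, global and local Moran's I, and aggregate peak analysis (APA).
    Seeded synthetic-data generators emulate every input type with planted
    structure so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
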