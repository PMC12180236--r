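# Brute-force oracles kept deliberately independent of the package's
# IRanges-backed implementations.

ivl_overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

brute_overlap <- function(a, b, slack = 0) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          ivl_overlaps(a$start[i] - slack, a$end[i] + slack,
                       b$start[j], b$end[j]))
        out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out))
    return(tibble::tibble(index_a = integer(), index_b = integer()))
  m <- do.call(rbind, out)
  tibble::tibble(index_a = m[, 1], index_b = m[, 2])
}

brute_pair_feature <- function(loops, features, slack = 0) {
  out <- list()
  for (i in seq_len(nrow(loops))) {
    for (j in seq_len(nrow(features))) {
      if (loops$chrom1[i] == features$chrom[j] &&
          ivl_overlaps(loops$start1[i] - slack, loops$end1[i] + slack,
                       features$start[j], features$end[j]))
        out[[length(out) + 1]] <- list(i, j, "A")
      if (loops$chrom2[i] == features$chrom[j] &&
          ivl_overlaps(loops$start2[i] - slack, loops$end2[i] + slack,
                       features$start[j], features$end[j]))
        out[[length(out) + 1]] <- list(i, j, "B")
    }
  }
  if (!length(out))
    return(tibble::tibble(loop_index = integer(), feature_index = integer(),
                          anchor = character()))
  tibble::tibble(loop_index = vapply(out, `[[`, 1L, 1),
                 feature_index = vapply(out, `[[`, 1L, 2),
                 anchor = vapply(out, `[[`, "", 3)) |>
    dplyr::arrange(loop_index, anchor, feature_index)
}

brute_pair_pair <- function(loops, pairs) {
  hit <- function(lc, ls, le, pc, ps, pe) lc == pc && ivl_overlaps(ls, le, ps, pe)
  out <- list()
  for (i in seq_len(nrow(loops))) {
    for (j in seq_len(nrow(pairs))) {
      a1 <- hit(loops$chrom1[i], loops$start1[i], loops$end1[i],
                pairs$chrom1[j], pairs$start1[j], pairs$end1[j])
      b2 <- hit(loops$chrom2[i], loops$start2[i], loops$end2[i],
                pairs$chrom2[j], pairs$start2[j], pairs$end2[j])
      a2 <- hit(loops$chrom1[i], loops$start1[i], loops$end1[i],
                pairs$chrom2[j], pairs$start2[j], pairs$end2[j])
      b1 <- hit(loops$chrom2[i], loops$start2[i], loops$end2[i],
                pairs$chrom1[j], pairs$start1[j], pairs$end1[j])
      if ((a1 && b2) || (a2 && b1)) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (!length(out))
    return(tibble::tibble(loop_index = integer(), pair_index = integer()))
  m <- do.call(rbind, out)
  tibble::tibble(loop_index = m[, 1], pair_index = m[, 2])
}

random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 50000,
                             max_len = 3000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(max_len, n, replace = TRUE))
}

random_loop_tbl <- function(n, chroms = c("c1", "c2"), max_pos = 50000,
                            width = 1000) {
  chrom <- sample(chroms, n, replace = TRUE)
  s1 <- sample.int(max_pos, n, replace = TRUE)
  gap <- sample.int(20000, n, replace = TRUE) + width
  tibble::tibble(chrom1 = chrom, start1 = s1, end1 = s1 + width,
                 chrom2 = chrom, start2 = s1 + gap,
                 end2 = s1 + gap + width,
                 q_value = runif(n, 1e-8, 1), resolution = width,
                 sample_id = "t")
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings), for exhaustive modularity maximization on small graphs.
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxval) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxval + 1)) rec(c(prefix, v), max(maxval, v))
  }
  rec(1L, 1L)
  out
}

# Unweighted Newman modularity of a membership vector.
modularity_hand <- function(edges, membership) {
  m <- nrow(edges)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = length(membership))
  q <- 0
  for (cc in unique(membership)) {
    nodes <- which(membership == cc)
    e_in <- sum(edges[, 1] %in% nodes & edges[, 2] %in% nodes)
    d_c <- sum(deg[nodes])
    q <- q + e_in / m - (d_c / (2 * m))^2
  }
  q
}

# Loop table for an explicit edge list: node i becomes the 5 kb anchor
# [i*5000, (i+1)*5000) on one synthetic chromosome.
loops_from_edges <- function(edges, q = 1e-10, chrom = "cg") {
  res <- 5000
  a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
  tibble::tibble(chrom1 = chrom, start1 = a * res, end1 = (a + 1) * res,
                 chrom2 = chrom, start2 = b * res, end2 = (b + 1) * res,
                 q_value = q, resolution = res, sample_id = "g")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
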