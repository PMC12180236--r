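# Regulatory loop networks: anchors become nodes labeled
# promoter/enhancer/other, loops become undirected edges weighted by
# -log10(q) capped at 20 and scaled to [0,1]; two-level Louvain communities
# per chromosome; connectivity-based community ranking.

#' Build a regulatory network from loops
#'
#' One node per unique anchor; anchors overlapping a TSS after +/-
#' `tss_slack` bp expansion are promoters (priority label), non-promoter
#' anchors overlapping a ChIP-seq peak (no slack) are enhancers, the rest
#' are "other". Edge weight is `-log10(q_value)` capped at `q_cap` (raw)
#' and divided by `q_cap` (scaled to \eqn{[0,1]}).
#'
#' @param loops Loop tibble from one sample, with q-values.
#' @param tss TSS tibble ([tss_from_genes()]).
#' @param peaks Peak tibble (may be empty).
#' @param tss_slack Promoter slack in bp (default 2500).
#' @param q_cap Cap on `-log10(q)` (default 20).
#' @return A `loop_network`: list with `graph` (igraph), `nodes`
#'   (`anchor_index, chrom, start, end, label`) and `edges`
#'   (`anchor_a, anchor_b, q_value, weight_raw, weight_scaled`).
#' @export
build_network <- function(loops, tss, peaks = NULL, tss_slack = 2500,
                          q_cap = 20) {
  if (any(is.na(loops$q_value))) abort("edge weights need q-values on all loops")
  uni <- anchor_universe(loops)
  anchors <- uni$anchors
  label <- rep("other", nrow(anchors))
  if (!is.null(peaks) && nrow(peaks) > 0) {
    hit_pk <- unique(intersect_with_slack(anchors, peaks, slack = 0)$index_a)
    label[hit_pk] <- "enhancer"
  }
  if (!is.null(tss) && nrow(tss) > 0) {
    hit_tss <- unique(intersect_with_slack(anchors, tss,
                                           slack = tss_slack)$index_a)
    label[hit_tss] <- "promoter"
  }
  nodes <- mutate(anchors, label = label)
  raw <- pmin(-log10(loops$q_value), q_cap)
  edges <- tibble(anchor_a = uni$loops$anchor_a,
                  anchor_b = uni$loops$anchor_b,
                  chrom = uni$loops$chrom,
                  q_value = loops$q_value,
                  weight_raw = raw,
                  weight_scaled = raw / q_cap)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$anchor_a, to = edges$anchor_b,
                   weight = edges$weight_scaled,
                   weight_raw = edges$weight_raw),
    directed = FALSE,
    vertices = data.frame(name = nodes$anchor_index, chrom = nodes$chrom,
                          start = nodes$start, end = nodes$end,
                          label = nodes$label))
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "loop_network")
}

#' @export
print.loop_network <- function(x, ...) {
  cat(sprintf("loop_network: %d nodes (%d promoter / %d enhancer / %d other), %d edges\n",
              nrow(x$nodes), sum(x$nodes$label == "promoter"),
              sum(x$nodes$label == "enhancer"),
              sum(x$nodes$label == "other"), nrow(x$edges)))
  invisible(x)
}

#' Two-level Louvain communities per chromosome
#'
#' Louvain modularity maximization is run on each chromosome's subgraph
#' (high level), then re-run inside each high-level community
#' (subcommunities). Community ids are `chrom:k` and `chrom:k.j`.
#'
#' @param network A `loop_network` from [build_network()].
#' @param seed Integer seed fixing the Louvain sweep order.
#' @return A `loop_communities`: list with `membership` (tibble
#'   `anchor_index, chrom, community, subcommunity`) and `communities`
#'   (tibble `community_id, level, parent, chrom, n_nodes`), plus
#'   `modularity` (tibble `chrom, modularity` of the high-level
#'   partitions).
#' @export
detect_communities <- function(network, seed = 1L) {
  g <- network$graph
  if (igraph::vcount(g) == 0) abort("empty graph")
  set.seed(seed)
  chroms <- sort(unique(igraph::V(g)$chrom))
  memb <- list(); comm <- list(); modq <- list()
  for (chr in chroms) {
    sub <- igraph::induced_subgraph(g, igraph::V(g)$chrom == chr)
    cl <- igraph::cluster_louvain(sub, weights = igraph::E(sub)$weight)
    m <- igraph::membership(cl)
    modq[[chr]] <- tibble(chrom = chr,
                          modularity = igraph::modularity(
                            sub, m, weights = igraph::E(sub)$weight))
    for (k in sort(unique(m))) {
      cid <- paste0(chr, ":", k)
      vs <- which(m == k)
      inner <- igraph::induced_subgraph(sub, vs)
      icl <- igraph::cluster_louvain(inner,
                                     weights = igraph::E(inner)$weight)
      im <- igraph::membership(icl)
      memb[[cid]] <- tibble(
        anchor_index = as.integer(igraph::V(inner)$name),
        chrom = chr, community = cid,
        subcommunity = paste0(cid, ".", as.integer(im)))
      comm[[cid]] <- bind_rows(
        tibble(community_id = cid, level = "high", parent = NA_character_,
               chrom = chr, n_nodes = length(vs)),
        tibble(community_id = paste0(cid, ".", sort(unique(as.integer(im)))),
               level = "sub", parent = cid, chrom = chr,
               n_nodes = as.integer(table(im)[as.character(
                 sort(unique(as.integer(im))))])))
    }
  }
  structure(list(membership = arrange(bind_rows(memb), .data$anchor_index),
                 communities = bind_rows(comm),
                 modularity = bind_rows(modq)),
            class = "loop_communities")
}

#' @export
print.loop_communities <- function(x, ...) {
  cat(sprintf("loop_communities: %d high-level, %d sub-level over %d nodes\n",
              sum(x$communities$level == "high"),
              sum(x$communities$level == "sub"), nrow(x$membership)))
  invisible(x)
}

community_metrics <- function(nodes, edges, weights) {
  n <- length(nodes)
  internal <- edges$anchor_a %in% nodes & edges$anchor_b %in% nodes
  boundary <- xor(edges$anchor_a %in% nodes, edges$anchor_b %in% nodes)
  m_in <- sum(internal)
  density <- if (n > 1) 2 * m_in / (n * (n - 1)) else 0
  w_in <- sum(weights[internal])
  w_bd <- sum(weights[boundary])
  conductance <- if (2 * w_in + w_bd > 0) w_bd / (2 * w_in + w_bd) else 0
  tibble(n_nodes = n, density = density, conductance = conductance,
         strength = w_in)
}

#' Rank communities by connectivity (Borda surrogate)
#'
#' Scores each community by aggregating internal edge density, conductance
#' (boundary leakage; lower is better) and weighted internal strength via
#' Borda rank aggregation within each level. This is a documented surrogate
#' for black-box community prioritization; the method tag is recorded in
#' the output.
#'
#' @param communities A `loop_communities` from [detect_communities()].
#' @param network The `loop_network` the communities came from.
#' @return A tibble `(community_id, level, n_nodes, density, conductance,
#'   strength, rank_score, method)`; higher `rank_score` ranks higher.
#' @export
rank_communities <- function(communities, network) {
  edges <- network$edges
  memb <- communities$membership
  rows <- bind_rows(pmap(communities$communities, function(community_id,
                                                           level, parent,
                                                           chrom, n_nodes) {
    nodes <- if (level == "high")
      memb$anchor_index[memb$community == community_id]
    else memb$anchor_index[memb$subcommunity == community_id]
    mutate(community_metrics(nodes, edges, edges$weight_scaled),
           community_id = community_id, level = level)
  }))
  rows |>
    group_by(.data$level) |>
    mutate(rank_score = (rank(.data$density, ties.method = "average") +
                           rank(-.data$conductance, ties.method = "average") +
                           rank(.data$strength, ties.method = "average")) /
             (3 * n())) |>
    ungroup() |>
    mutate(method = "borda_surrogate") |>
    select("community_id", "level", "n_nodes", "density", "conductance",
           "strength", "rank_score", "method") |>
    arrange(.data$level, desc(.data$rank_score))
}

#' Tidy membership of a community object
#' @param x A `loop_communities`.
#' @param ... Unused.
#' @return The membership tibble.
#' @export
tidy.loop_communities <- function(x, ...) x$membership

#' One-row summary of a community detection run
#' @param x A `loop_communities`.
#' @param ... Unused.
#' @return A tibble with community counts and mean high-level modularity.
#' @export
glance.loop_communities <- function(x, ...) {
  tibble(n_high = sum(x$communities$level == "high"),
         n_sub = sum(x$communities$level == "sub"),
         n_nodes = nrow(x$membership),
         mean_modularity = mean(x$modularity$modularity))
}

#' Export a network in GraphML format
#' @param network A `loop_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
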