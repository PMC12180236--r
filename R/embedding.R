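# 2D chromatin embeddings: log10/reciprocal contact transform, Kamada-Kawai
# layout, bounded Voronoi spatial weights, and global/local Moran's I.

#' Transform contact counts to layout distances
#'
#' Counts are log10-transformed; transformed values below the assay
#' threshold (0.1 for HiChIP, 1 for Hi-C) are set to zero; distances are
#' the reciprocal of the remaining values, with `Inf` (no edge) where the
#' transformed count is zero.
#'
#' @param mat Symmetric non-negative contact matrix.
#' @param assay `"hichip"` or `"hic"` (sets the low-count threshold).
#' @return A symmetric distance matrix (`Inf` = no edge, diagonal 0).
#' @export
transform_contacts <- function(mat, assay = c("hichip", "hic")) {
  assay <- match.arg(assay)
  if (any(mat < 0)) abort("contact counts must be >= 0")
  thr <- if (assay == "hichip") 0.1 else 1
  t <- suppressWarnings(log10(mat))
  t[!is.finite(t) | t < thr] <- 0
  if (all(t[upper.tri(t)] == 0)) abort("all contacts below threshold: no graph")
  d <- ifelse(t > 0, 1 / t, Inf)
  diag(d) <- 0
  d
}

#' Kamada-Kawai 2D layout of a distance matrix
#'
#' Builds a graph from the finite off-diagonal distances and minimizes
#' Kamada-Kawai stress with edge weights as target distances. The layout is
#' deterministic: nodes are initialized on a circle in genomic (index)
#' order. Disconnected bins outside the largest connected component are
#' dropped and reported.
#'
#' @param distances Symmetric distance matrix from [transform_contacts()].
#' @return An `embedding2d`: list with `coords` (tibble `bin, x, y`; `bin`
#'   is the 1-based row index in `distances`) and `dropped` (integer bins
#'   not embedded).
#' @export
layout_kk <- function(distances) {
  n <- nrow(distances)
  idx <- which(upper.tri(distances) & is.finite(distances), arr.ind = TRUE)
  if (nrow(idx) == 0) abort("no finite distances: nothing to embed")
  g <- igraph::graph_from_data_frame(
    data.frame(from = idx[, 1], to = idx[, 2],
               weight = distances[idx]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  keep_comp <- which.max(comp$csize)
  keep <- which(comp$membership == keep_comp)
  dropped <- setdiff(seq_len(n), keep)
  if (length(dropped))
    warn(paste0("dropped ", length(dropped),
                " bin(s) outside the largest connected component"))
  sub <- igraph::induced_subgraph(g, keep)
  m <- igraph::vcount(sub)
  init <- cbind(cos(2 * pi * seq_len(m) / m), sin(2 * pi * seq_len(m) / m))
  co <- igraph::layout_with_kk(sub, coords = init, dim = 2,
                               weights = igraph::E(sub)$weight)
  structure(list(coords = tibble(bin = as.integer(igraph::V(sub)$name),
                                 x = co[, 1], y = co[, 2]),
                 dropped = dropped),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("embedding2d: %d bins embedded, %d dropped\n",
              nrow(x$coords), length(x$dropped)))
  invisible(x)
}

#' Voronoi spatial weights from 2D coordinates
#'
#' Tessellates the points into Voronoi cells bounded by the coordinate
#' bounding box padded by `pad` of its range; `w_ij = 1` when cells i and j
#' share an edge, then rows are standardized to sum to one. Duplicate or
#' collinear point sets fall back to a small deterministic jitter with a
#' warning.
#'
#' @param coords Tibble with `x, y` (e.g. `embedding2d$coords`) or a
#'   two-column matrix.
#' @param pad Fractional padding of the bounding box (default 0.1).
#' @return A list: `W` (row-standardized weight matrix, zero diagonal) and
#'   `adjacency` (logical matrix).
#' @export
voronoi_weights <- function(coords, pad = 0.1) {
  if (is.data.frame(coords)) coords <- cbind(coords$x, coords$y)
  n <- nrow(coords)
  if (n < 3) abort("need at least 3 points")
  x <- coords[, 1]; y <- coords[, 2]
  degenerate <- anyDuplicated(cbind(x, y)) > 0 ||
    abs(sd(x)) < 1e-12 || abs(sd(y)) < 1e-12 ||
    abs(cor(x, y)) > 1 - 1e-12
  if (degenerate) {
    warn("degenerate point configuration: applying deterministic jitter")
    scale <- max(diff(range(x)), diff(range(y)), 1) * 1e-6
    x <- x + scale * cos(7 * seq_len(n))
    y <- y + scale * sin(11 * seq_len(n))
  }
  rx <- range(x); ry <- range(y)
  px <- max(diff(rx), 1e-9) * pad; py <- max(diff(ry), 1e-9) * pad
  adj <- voronoi_adjacency(x, y, rx[1] - px, rx[2] + px,
                           ry[1] - py, ry[2] + py)
  W <- adj * 1
  rs <- rowSums(W)
  W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  list(W = W, adjacency = adj)
}

moran_global_stat <- function(z, W) {
  n <- length(z)
  (n / sum(W)) * sum(z * (W %*% z)) / sum(z^2)
}

#' Global Moran's I with permutation inference
#'
#' \eqn{I = (N/S_0) \sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2} with
#' \eqn{z = x - \bar x}. The p-value is one-sided for clustering: the signal
#' is permuted over bins `n_perm` times and
#' `p = (1 + #(I_perm >= I_obs)) / (1 + n_perm)`.
#'
#' @param signal Per-bin signal vector (positive variance required).
#' @param W Row-standardized spatial weight matrix.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A `global_moran` list: `I`, `expected` (`-1/(N-1)`), `p_value`,
#'   `n_perm`, `perms` (the permuted statistics).
#' @export
global_moran <- function(signal, W, n_perm = 999, seed = NULL) {
  n <- length(signal)
  if (n != nrow(W)) abort("signal length must match W")
  if (sd(signal) == 0) abort("signal has zero variance")
  if (!is.null(seed)) set.seed(seed)
  z <- signal - mean(signal)
  I_obs <- moran_global_stat(z, W)
  Zp <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
  Ip <- (n / sum(W)) * colSums(Zp * (W %*% Zp)) / sum(z^2)
  p <- (1 + sum(Ip >= I_obs)) / (1 + n_perm)
  structure(list(I = I_obs, expected = -1 / (n - 1), p_value = p,
                 n_perm = n_perm, perms = Ip),
            class = "global_moran")
}

#' @export
print.global_moran <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f, p = %.4g, %d perms)\n",
              x$I, x$expected, x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname global_moran
#' @param x A `global_moran`.
#' @param ... Unused.
#' @export
glance.global_moran <- function(x, ...) {
  tibble(I = x$I, expected = x$expected, p_value = x$p_value,
         n_perm = x$n_perm)
}

#' Local Moran's I with conditional permutation inference
#'
#' \eqn{I_i = (z_i / m_2) \sum_j w_{ij} z_j} with
#' \eqn{m_2 = \sum_k z_k^2 / N}. Each bin's p-value comes from conditional
#' permutation (its own value held fixed, neighbors resampled from the
#' remaining bins); the reported `p_sim` is the one-sided probability of
#' the more extreme tail. Quadrants combine the sign of \eqn{z_i} and of
#' the spatial lag: HH, HL, LH, LL.
#'
#' @param signal Per-bin signal vector.
#' @param W Row-standardized spatial weight matrix.
#' @param n_perm Number of conditional permutations per bin (default 999).
#' @param seed Optional integer seed.
#' @return A tibble `(bin, local_i, p_sim, quadrant, z, lag)`. The mean of
#'   `local_i` equals the global I under row-standardized weights.
#' @export
local_moran <- function(signal, W, n_perm = 999, seed = NULL) {
  n <- length(signal)
  if (n != nrow(W)) abort("signal length must match W")
  if (sd(signal) == 0) abort("signal has zero variance")
  if (!is.null(seed)) set.seed(seed)
  z <- signal - mean(signal)
  m2 <- sum(z^2) / n
  lag <- as.numeric(W %*% z)
  li <- z / m2 * lag
  p_sim <- vapply(seq_len(n), function(i) {
    nz <- which(W[i, ] > 0)
    if (!length(nz)) return(NA_real_)
    wi <- W[i, nz]
    others <- z[-i]
    k <- length(nz)
    perm_lag <- vapply(seq_len(n_perm), function(s) {
      sum(others[sample.int(length(others), k)] * wi)
    }, numeric(1))
    perm_i <- z[i] / m2 * perm_lag
    larger <- sum(perm_i >= li[i])
    larger <- min(larger, n_perm - larger)
    (larger + 1) / (n_perm + 1)
  }, numeric(1))
  quadrant <- paste0(if_else(z > 0, "H", "L"),
                     if_else(lag > 0, "H", "L"))
  tibble(bin = seq_len(n), local_i = li, p_sim = p_sim,
         quadrant = quadrant, z = z, lag = lag)
}

#' Full spatial-autocorrelation analysis of an embedded signal
#'
#' Convenience wrapper: Voronoi weights from an embedding, then global and
#' local Moran's I of the signal restricted to the embedded bins.
#'
#' @param embedding An `embedding2d` from [layout_kk()].
#' @param signal Per-bin signal for ALL bins of the original window (the
#'   embedded subset is selected internally).
#' @param n_perm Permutations for both analyses.
#' @param seed Optional integer seed.
#' @return A `moran_result`: list with `global` (`global_moran`), `local`
#'   (tibble), `weights`, and `coords`.
#' @export
moran_analysis <- function(embedding, signal, n_perm = 999, seed = NULL) {
  sig <- signal[embedding$coords$bin]
  vw <- voronoi_weights(embedding$coords)
  g <- global_moran(sig, vw$W, n_perm = n_perm, seed = seed)
  l <- local_moran(sig, vw$W, n_perm = n_perm, seed = seed)
  l$bin <- embedding$coords$bin
  structure(list(global = g, local = l, weights = vw,
                 coords = embedding$coords, signal = sig),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  print(x$global)
  cat(sprintf("local: %d bins, %d significant at p <= 0.05\n",
              nrow(x$local), sum(x$local$p_sim <= 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Per-bin local Moran table
#' @param x A `moran_result`.
#' @param ... Unused.
#' @return The local Moran tibble.
#' @export
tidy.moran_result <- function(x, ...) x$local

#' One-row global Moran summary
#' @param x A `moran_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.moran_result <- function(x, ...) glance(x$global)
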