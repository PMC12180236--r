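# Stratum-adjusted correlation coefficient (SCC) for pairs of binned
# contact matrices, HiCRep-style: mean-filter smoothing, per-diagonal
# Pearson correlation, variance-weighted combination.

#' Mean-filter smoothing of a contact matrix
#'
#' Applies a (2h+1) x (2h+1) uniform (box) mean filter; windows are
#' truncated at matrix edges (mean over available cells). `h = 0` returns
#' the matrix unchanged.
#'
#' @param mat Numeric matrix.
#' @param h Non-negative integer smoothing half-width.
#' @return The smoothed matrix.
#' @export
smooth_matrix <- function(mat, h) {
  if (h < 0) abort("h must be >= 0")
  if (h == 0) return(mat)
  sm1 <- function(m, h) {
    # running mean along rows with edge truncation, via padded cumsums
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(n, seq_len(n) + h); lo <- pmax(0, seq_len(n) - h - 1)
    (cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) / (hi - lo)
  }
  t(sm1(t(sm1(mat, h)), h))
}

#' Stratum-adjusted correlation coefficient of two contact matrices
#'
#' Both matrices are smoothed with a (2h+1) x (2h+1) mean filter, a Pearson
#' correlation \eqn{r_d} is computed within each diagonal stratum
#' \eqn{d = 0..max_dist_bins} having nonzero variance in both matrices, and
#' the SCC is the weighted combination
#' \eqn{\sum_d w_d r_d / \sum_d w_d} with \eqn{w_d = N_d \sigma_{a,d}
#' \sigma_{b,d}}.
#'
#' @param mat_a,mat_b Square contact matrices on identical bin grids.
#' @param h Smoothing half-width (integer >= 0).
#' @param max_dist_bins Largest diagonal offset (in bins) to include;
#'   defaults to all.
#' @return An object of class `scc_result`: list with `scc`, `h`,
#'   `strata_used`, `strata_skipped`.
#' @export
scc <- function(mat_a, mat_b, h = 0, max_dist_bins = nrow(mat_a) - 1L) {
  if (!all(dim(mat_a) == dim(mat_b)) || nrow(mat_a) != ncol(mat_a))
    abort("matrices must be square and on identical bin grids")
  a <- smooth_matrix(mat_a, h)
  b <- smooth_matrix(mat_b, h)
  n <- nrow(a)
  max_dist_bins <- min(max_dist_bins, n - 1L)
  used <- 0L; skipped <- 0L
  wsum <- 0; wr <- 0
  for (d in 0:max_dist_bins) {
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    xa <- a[idx]; xb <- b[idx]
    if (length(xa) < 2) { skipped <- skipped + 1L; next }
    sa <- sd(xa); sb <- sd(xb)
    if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) {
      skipped <- skipped + 1L; next
    }
    r <- cor(xa, xb)
    w <- length(xa) * sa * sb
    wr <- wr + w * r
    wsum <- wsum + w
    used <- used + 1L
  }
  if (used == 0L) abort("no usable strata (zero variance everywhere)")
  structure(list(scc = wr / wsum, h = h, strata_used = used,
                 strata_skipped = skipped),
            class = "scc_result")
}

#' @export
print.scc_result <- function(x, ...) {
  cat(sprintf("SCC = %.4f (h = %d, %d strata used, %d skipped)\n",
              x$scc, x$h, x$strata_used, x$strata_skipped))
  invisible(x)
}

#' @rdname scc
#' @param x An `scc_result`.
#' @param ... Unused.
#' @export
glance.scc_result <- function(x, ...) {
  tibble(scc = x$scc, h = x$h, strata_used = x$strata_used,
         strata_skipped = x$strata_skipped)
}

#' Grid-search trainer for the SCC smoothing half-width
#'
#' Scans `h = 0..h_max` and returns the smallest `h` whose SCC gain over the
#' previous value drops below `tol` (or the argmax if gains never flatten),
#' mirroring how replicate pairs are used to pick a smoothing level before
#' the merge decision.
#'
#' @param mat_a,mat_b Contact matrices.
#' @param h_max Largest half-width scanned (default 25).
#' @param max_dist_bins Passed to [scc()].
#' @param tol Minimum SCC improvement to keep increasing `h`.
#' @return The selected integer `h`.
#' @export
scc_train <- function(mat_a, mat_b, h_max = 25, max_dist_bins = nrow(mat_a) - 1L,
                      tol = 0.01) {
  prev <- scc(mat_a, mat_b, h = 0, max_dist_bins = max_dist_bins)$scc
  best_h <- 0L
  for (h in seq_len(h_max)) {
    cur <- scc(mat_a, mat_b, h = h, max_dist_bins = max_dist_bins)$scc
    if (cur - prev < tol) return(best_h)
    prev <- cur
    best_h <- h
  }
  best_h
}

#' Replicate merge decision from pairwise SCCs
#'
#' A replicate group is merged only when every pairwise SCC strictly
#' exceeds the threshold (default 0.8). A single replicate has no pairs and
#' merges vacuously (with a warning).
#'
#' @param sccs Numeric vector of pairwise SCC values (or a list of
#'   `scc_result` objects) covering all `choose(n, 2)` pairs.
#' @param n_replicates Number of replicates in the group.
#' @param threshold Merge threshold (strict `>`).
#' @return `TRUE` to merge, `FALSE` otherwise.
#' @export
merge_decision <- function(sccs, n_replicates, threshold = 0.8) {
  if (is.list(sccs)) sccs <- map_dbl(sccs, function(x) x$scc)
  expected <- choose(n_replicates, 2)
  if (expected == 0) {
    warn("single replicate: merge decision is vacuously TRUE")
    return(TRUE)
  }
  if (length(sccs) != expected)
    abort(sprintf("expected %d pairwise SCCs for %d replicates, got %d",
                  expected, n_replicates, length(sccs)))
  all(sccs > threshold)
}
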