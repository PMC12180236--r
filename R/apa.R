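# Aggregate peak analysis: mean submatrix over loop pixels; APA score =
# center over the distal corner block (15-30 kb offsets), APA ratio =
# center over all non-center pixels.

#' Aggregate peak analysis over loop pixels
#'
#' Submatrices centered on each loop's bin pair are aggregated by the mean.
#' The APA score divides the center pixel by the mean of the corner block
#' lying `corner_lo`..`corner_hi` bp downstream of the upstream locus and
#' the same range upstream of the downstream locus (offsets
#' `floor(corner_lo/res)`..`floor(corner_hi/res)` bins, i.e. 3..6 at 5 kb).
#' The APA ratio divides the center pixel by the mean of all non-center
#' pixels.
#'
#' @param mat Symmetric contact matrix.
#' @param loop_bins Tibble `(bin_a, bin_b)` of 1-based bin indices of loop
#'   pixels, with `bin_a < bin_b` (upstream locus first).
#' @param resolution Bin size in bp.
#' @param corner_lo,corner_hi Corner-block offset range in bp (defaults
#'   15000 and 30000).
#' @return An `apa_result`: list with `apa_score`, `apa_ratio`,
#'   `agg_matrix`, `n_used`, `n_skipped` (loops whose window fell outside
#'   the matrix).
#' @export
apa <- function(mat, loop_bins, resolution, corner_lo = 15000,
                corner_hi = 30000) {
  off_lo <- floor(corner_lo / resolution)
  off_hi <- floor(corner_hi / resolution)
  if (off_lo < 1 || off_hi <= off_lo)
    abort("corner offsets degenerate at this resolution")
  w <- off_hi
  n <- nrow(mat)
  agg <- matrix(0, 2 * w + 1, 2 * w + 1)
  used <- 0L; skipped <- 0L
  for (r in seq_len(nrow(loop_bins))) {
    i <- loop_bins$bin_a[r]; j <- loop_bins$bin_b[r]
    if (i - w < 1 || i + w > n || j - w < 1 || j + w > n) {
      skipped <- skipped + 1L
      next
    }
    agg <- agg + mat[(i - w):(i + w), (j - w):(j + w)]
    used <- used + 1L
  }
  if (used == 0L) abort("no loop window fits inside the matrix")
  agg <- agg / used
  c0 <- w + 1
  center <- agg[c0, c0]
  corner <- agg[(c0 + off_lo):(c0 + off_hi), (c0 - off_hi):(c0 - off_lo)]
  rest_mean <- (sum(agg) - center) / (length(agg) - 1)
  structure(list(apa_score = center / mean(corner),
                 apa_ratio = center / rest_mean,
                 agg_matrix = agg, n_used = used, n_skipped = skipped,
                 flank_bins = w),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA: score = %.3f, ratio = %.3f (%d loops used, %d skipped)\n",
              x$apa_score, x$apa_ratio, x$n_used, x$n_skipped))
  invisible(x)
}

#' One-row APA summary
#' @param x An `apa_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.apa_result <- function(x, ...) {
  tibble(apa_score = x$apa_score, apa_ratio = x$apa_ratio,
         n_used = x$n_used, n_skipped = x$n_skipped)
}

#' Map loops to bin indices of a contact window
#'
#' @param loops Loop tibble whose anchors lie on the window's bin grid.
#' @param window_start Genomic start (0-based) of bin 1.
#' @param resolution Bin size in bp.
#' @return A tibble `(bin_a, bin_b)` of 1-based bin indices.
#' @export
loops_to_bins <- function(loops, window_start, resolution) {
  tibble(bin_a = as.integer((loops$start1 - window_start) %/% resolution) + 1L,
         bin_b = as.integer((loops$start2 - window_start) %/% resolution) + 1L)
}
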