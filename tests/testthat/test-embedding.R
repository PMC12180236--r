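cycle_W <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, (i %% n) + 1] <- 0.5
    W[i, ((i - 2) %% n) + 1] <- 0.5
  }
  W
}

test_that("contact transform applies assay thresholds and reciprocals", {
  m <- matrix(c(0, 100, 100, 0), 2)
  d <- transform_contacts(m, "hichip")
  expect_equal(d[1, 2], 1 / 2)  # log10(100) = 2 -> d = 0.5
  # log10 value below the HiChIP threshold is zeroed -> no edge
  m2 <- matrix(c(0, 10^0.05, 10, 10^0.05, 0, 100, 10, 100, 0), 3)
  d2 <- transform_contacts(m2, "hichip")
  expect_equal(d2[1, 2], Inf)
  expect_equal(d2[1, 3], 1)
  # Hi-C threshold is 1: log10 in [0.1, 1) survives HiChIP but not Hi-C
  m3 <- matrix(c(0, 10^0.5, 10^0.5, 0), 2)
  expect_equal(transform_contacts(m3, "hichip")[1, 2], 2)
  expect_error(transform_contacts(m3, "hic"), "no graph")
  expect_true(isSymmetric(d2))
  expect_error(transform_contacts(matrix(0, 3, 3)), "no graph")
})

test_that("equal pairwise distances embed as an equilateral triangle", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  emb <- layout_kk(d)
  co <- cbind(emb$coords$x, emb$coords$y)
  dd <- as.numeric(dist(co))
  expect_equal(max(dd) / min(dd), 1, tolerance = 1e-6)
})

test_that("doubling distances scales the layout without changing shape", {
  set.seed(6)
  w <- synth_contact_window(n_bins = 40, seed = 6)
  d <- transform_contacts(w$mat, "hichip")
  e1 <- layout_kk(d)
  e2 <- layout_kk(d * 2)
  expect_equal(e1$coords$bin, e2$coords$bin)
  a <- cbind(e1$coords$x, e1$coords$y)
  b <- cbind(e2$coords$x, e2$coords$y)
  # Procrustes: center, best rotation from SVD, compare residual
  a <- scale(a, scale = FALSE); b <- scale(b, scale = FALSE)
  s <- svd(crossprod(b, a))
  rot <- s$u %*% t(s$v)
  scale_fac <- sum((b %*% rot) * a) / sum(a^2)
  resid <- sum((b %*% rot - scale_fac * a)^2) / sum(b^2)
  expect_lt(resid, 1e-6)
})

test_that("layouts are deterministic and report dropped bins", {
  w <- synth_contact_window(n_bins = 50, seed = 7)
  d <- transform_contacts(w$mat, "hichip")
  e1 <- layout_kk(d)
  e2 <- layout_kk(d)
  expect_identical(e1, e2)
  # isolate one bin
  d2 <- d
  d2[5, ] <- Inf; d2[, 5] <- Inf; diag(d2) <- 0
  expect_warning(e3 <- layout_kk(d2), "dropped")
  expect_equal(e3$dropped, 5L)
})

test_that("2x2 grid of points yields rook-contiguity Voronoi weights", {
  pts <- tibble::tibble(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  vw <- voronoi_weights(pts)
  expect_equal(diag(vw$W), rep(0, 4))
  expect_equal(rowSums(vw$W), rep(1, 4))
  expect_true(isSymmetric(vw$adjacency * 1))
  # diagonal neighbors meet only at a point -> not adjacent
  expect_equal(rowSums(vw$adjacency), rep(2, 4))
  expect_false(vw$adjacency[1, 4])
  expect_false(vw$adjacency[2, 3])
})

test_that("collinear points trigger the jitter fallback", {
  pts <- tibble::tibble(x = 1:5, y = 2 * (1:5))
  expect_warning(vw <- voronoi_weights(pts), "jitter")
  expect_equal(rowSums(vw$W), rep(1, 5))
})

test_that("alternating signal on an even cycle gives I = -1 exactly", {
  n <- 12
  W <- cycle_W(n)
  sig <- rep(c(1, -1), n / 2)
  g <- global_moran(sig, W, n_perm = 99, seed = 1)
  expect_equal(g$I, -1, tolerance = 1e-12)
  expect_equal(g$expected, -1 / (n - 1))
})

test_that("permutation mean of I matches -1/(N-1) and local sums to global", {
  set.seed(12)
  w <- synth_contact_window(n_bins = 60, seed = 12)
  emb <- layout_kk(transform_contacts(w$mat, "hichip"))
  vw <- voronoi_weights(emb$coords)
  sig <- w$signal[emb$coords$bin]
  g <- global_moran(sig, vw$W, n_perm = 2000, seed = 3)
  mc_se <- sd(g$perms) / sqrt(g$n_perm)
  expect_lt(abs(mean(g$perms) - g$expected), 4 * mc_se)
  loc <- local_moran(sig, vw$W, n_perm = 19, seed = 3)
  expect_equal(mean(loc$local_i), g$I, tolerance = 1e-9)
})

test_that("Moran I is invariant to positive affine transforms of the signal", {
  set.seed(13)
  W <- cycle_W(10)
  sig <- rnorm(10)
  g1 <- global_moran(sig, W, n_perm = 9, seed = 1)
  g2 <- global_moran(3.2 * sig + 7, W, n_perm = 9, seed = 1)
  expect_equal(g1$I, g2$I, tolerance = 1e-9)
})

test_that("smooth gradients cluster (I > 0, small p) and quadrants obey signs", {
  n <- 30
  W <- cycle_W(n)  # path-like neighborhood on a cycle
  sig <- sin(2 * pi * seq_len(n) / n)  # smooth gradient
  g <- global_moran(sig, W, n_perm = 999, seed = 2)
  expect_gt(g$I, 0)
  expect_lte(g$p_value, 0.01)
  loc <- local_moran(sig, W, n_perm = 99, seed = 2)
  z <- sig - mean(sig)
  lag <- as.numeric(W %*% z)
  expect_equal(loc$quadrant,
               paste0(ifelse(z > 0, "H", "L"), ifelse(lag > 0, "H", "L")))
  # planted hotspot: HH bins coincide with the high block
  w <- synth_contact_window(n_bins = 80, seed = 14, block = 31:45,
                            block_height = 5)
  emb <- layout_kk(transform_contacts(w$mat, "hichip"))
  mor <- moran_analysis(emb, w$signal, n_perm = 199, seed = 5)
  sig_bins <- mor$local$bin[mor$local$p_sim <= 0.05 &
                              mor$local$quadrant == "HH"]
  expect_gt(length(intersect(sig_bins, 31:45)), 0)
  expect_true(mean(sig_bins %in% 31:45) > 0.8)
})

test_that("APA is exact on constant and center-spiked matrices", {
  m <- matrix(2, 100, 100)
  lb <- tibble::tibble(bin_a = c(30, 40), bin_b = c(80, 95))
  r <- apa(m, lb, resolution = 5000)
  expect_equal(r$apa_score, 1)
  expect_equal(r$apa_ratio, 1)
  m2 <- matrix(2, 100, 100)
  m2[30, 80] <- 6  # 3c over constant background c
  r2 <- apa(m2, tibble::tibble(bin_a = 30, bin_b = 80), resolution = 5000)
  expect_equal(r2$apa_score, 3)
  # scaling equivariance
  r3 <- apa(m2 * 10, tibble::tibble(bin_a = 30, bin_b = 80),
            resolution = 5000)
  expect_equal(r3$apa_score, r2$apa_score)
  expect_equal(r3$apa_ratio, r2$apa_ratio)
  # edge loops are skipped with a count
  r4 <- apa(m2, tibble::tibble(bin_a = c(30, 2), bin_b = c(80, 99)),
            resolution = 5000)
  expect_equal(r4$n_skipped, 1L)
})

test_that("planted enrichment is recovered by APA within 10%", {
  w <- synth_contact_window(seed = 21, enrichment = 3)
  r <- apa(w$mat, w$loop_bins, resolution = w$resolution)
  expect_equal(r$apa_score, 3, tolerance = 0.1)
})
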