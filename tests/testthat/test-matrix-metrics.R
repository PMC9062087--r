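test_that("ICE fixes an already-balanced matrix in one iteration", {
  bins <- bins1(6, 100)
  # circulant: every marginal equal
  mat <- matrix(1, 6, 6) + diag(6)
  m <- cm_from_dense(bins, mat, kind = "raw")
  out <- ice_normalize(m, coverage_filter_fraction = 0)
  expect_true(out$converged)
  expect_equal(out$iterations, 1)
  expect_equal(out$bias, rep(1, 6))
})

test_that("ICE recovers a planted bias vector up to scale", {
  set.seed(42)
  n <- 120
  bins <- bins1(n, 1e5)
  b <- exp(runif(n, log(0.5), log(2)))
  base <- matrix(5, n, n)            # balanced template
  w <- base * outer(b, b)
  m <- cm_from_dense(bins, w, kind = "raw")
  out <- ice_normalize(m, coverage_filter_fraction = 0)
  expect_true(out$converged)
  expect_gt(stats::cor(log(out$bias), log(b)), 0.999)
  s <- cm_marginals(out$matrix)
  expect_lt(stats::sd(s, na.rm = TRUE) / mean(s, na.rm = TRUE), 1e-4)
})

test_that("ICE masks zero-coverage bins and balances the rest", {
  n <- 30
  bins <- bins1(n, 1e5)
  mat <- matrix(3, n, n)
  mat[5, ] <- 0; mat[, 5] <- 0
  m <- cm_from_dense(bins, mat, kind = "raw")
  out <- ice_normalize(m, coverage_filter_fraction = 0)
  expect_true(out$mask[5])
  expect_true(is.na(out$bias[5]))
  s <- cm_marginals(out$matrix)
  expect_lt(stats::sd(s, na.rm = TRUE) / mean(s, na.rm = TRUE), 1e-4)
})

test_that("ICE is idempotent and errors when everything is masked", {
  set.seed(1)
  n <- 50
  bins <- bins1(n, 1e5)
  w <- matrix(rpois(n * n, 20), n, n); w <- w + t(w)
  m <- cm_from_dense(bins, w, kind = "raw")
  out1 <- ice_normalize(m, coverage_filter_fraction = 0)
  out2 <- ice_normalize(out1$matrix, coverage_filter_fraction = 0)
  expect_lt(max(abs(out2$matrix$mat - out1$matrix$mat)), 1e-3)
  empty <- cm_from_dense(bins, matrix(0, n, n) + 0 * diag(n), kind = "raw")
  expect_error(ice_normalize(empty), "masked")
})

test_that("expected-by-distance averages over unmasked pairs", {
  n <- 10
  bins <- bins1(n, 1e5)
  f <- function(d) 2^(-d)
  mat <- outer(1:n, 1:n, function(i, j) f(abs(i - j)))
  m <- cm_from_dense(bins, mat)
  e <- expected_by_distance(m, "chr1")
  expect_equal(e[1:4], f(0:3))
  oe <- observed_over_expected(m)
  tp <- hicpair:::cm_triplets(oe)
  expect_true(all(abs(tp$x - 1) < 1e-12))

  # single nonzero at distance 3: E(3) = value / number of pairs at d = 3
  mat2 <- matrix(0, n, n); mat2[2, 5] <- mat2[5, 2] <- 14
  m2 <- cm_from_dense(bins, mat2)
  expect_equal(expected_by_distance(m2, "chr1")[4], 14 / 7)

  # masked bin leaves both numerator and denominator
  m3 <- cm_apply_mask(m, c(TRUE, rep(FALSE, n - 1)))
  e3 <- expected_by_distance(m3, "chr1")
  expect_equal(e3[4], f(3))              # still exact on remaining pairs
  expect_error(observed_over_expected(cm_from_dense(bins, matrix(0, n, n))),
               "empty")
})

test_that("cis/trans totals and fractions are bookkept correctly", {
  g <- genome_spec(c("chr1", "chr2"), c(3e5, 3e5))
  bins <- bin_genome(g, 1e5)
  m <- contact_matrix(bins, i = c(0, 1, 0), j = c(1, 2, 3),
                      x = c(500, 400, 100), kind = "raw")
  ct <- cis_trans_ratio(m)
  expect_equal(ct$cis, 900)
  expect_equal(ct$trans, 100)
  expect_equal(ct$trans_fraction, 0.10)
  m_cis <- contact_matrix(bins, i = 0, j = 1, x = 5, kind = "raw")
  expect_equal(cis_trans_ratio(m_cis)$trans_fraction, 0)
})

test_that("decay exponents are exact on exact power laws", {
  n <- 600                                 # 30 Mb at 50 kb: all segments hit
  bins <- bins1(n, 5e4)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  m <- contact_matrix(bins, i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                      x = (d * 5e4)^(-1), kind = "normalized")
  dc <- decay_curve(m)
  expect_true(all(dc$segments$ok))
  expect_true(all(abs(dc$segments$exponent - (-1)) < 1e-9))

  # flat contact: exponent 0
  mf <- contact_matrix(bins, i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                       x = rep(2, nrow(idx)), kind = "normalized")
  dcf <- decay_curve(mf)
  expect_true(all(abs(dcf$segments$exponent) < 1e-12))

  # global scaling leaves O/E and exponents unchanged
  m2 <- contact_matrix(bins, i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                       x = 3.7 * (d * 5e4)^(-1), kind = "normalized")
  expect_equal(decay_curve(m2)$segments$exponent, dc$segments$exponent)
})

test_that("a sparse segment is flagged instead of fitted", {
  n <- 80                                   # 40 Mb at 500 kb
  bins <- bins1(n, 5e5)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  m <- contact_matrix(bins, i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                      x = (d * 5e5)^(-1), kind = "normalized")
  dc <- decay_curve(m)
  sub_mb <- dc$segments[dc$segments$name == "0.1-1Mb", ]
  expect_false(sub_mb$ok)                   # only d = 1, 2 exist at 500 kb
  expect_true(is.na(sub_mb$exponent))
})

test_that("cumulative cis curve is monotone and ends at 1", {
  set.seed(7)
  n <- 50
  bins <- bins1(n, 1e5)
  w <- matrix(rpois(n * n, 4), n, n); w <- w + t(w)
  m <- cm_from_dense(bins, w, kind = "raw")
  cc <- cumulative_cis_by_distance(m)
  expect_true(all(diff(cc$cumulative) >= 0))
  expect_equal(cc$fraction[nrow(cc)], 1)
})

test_that("chromosome clustering recovers a planted partition", {
  g <- genome_spec(paste0("chr", 1:6), rep(5e5, 6))
  bins <- bin_genome(g, 1e5)
  n <- nrow(bins)
  mat <- matrix(0, n, n)
  grp <- list(c("chr1", "chr2", "chr3"), c("chr4", "chr5", "chr6"))
  for (a in 1:6) for (b in 1:6) {
    if (a == b) next
    ra <- which(bins$chrom == paste0("chr", a))
    rb <- which(bins$chrom == paste0("chr", b))
    same <- any(vapply(grp, function(gg)
      all(paste0("chr", c(a, b)) %in% gg), logical(1)))
    mat[ra, rb] <- if (same) 10 else 1
  }
  set.seed(3)
  mat <- mat + matrix(runif(n * n, 0, 0.1), n, n)
  mat[lower.tri(mat)] <- t(mat)[lower.tri(mat)]
  m <- cm_from_dense(bins, mat)
  cl <- chromosome_cluster(m)
  part <- stats::cutree(cl$hclust, k = 2)
  expect_equal(part[["chr1"]], part[["chr2"]])
  expect_equal(part[["chr1"]], part[["chr3"]])
  expect_equal(part[["chr4"]], part[["chr5"]])
  expect_false(part[["chr1"]] == part[["chr4"]])

  # identical rows correlate perfectly
  expect_equal(unname(cl$correlation["chr1", "chr2"]), 1, tolerance = 0.05)

  # permuting chromosome order leaves the partition intact
  g2 <- genome_spec(paste0("chr", c(4, 1, 5, 2, 6, 3)), rep(5e5, 6))
  bins2 <- bin_genome(g2, 1e5)
  map <- match(paste(bins2$chrom, bins2$start), paste(bins$chrom, bins$start))
  m2 <- cm_from_dense(bins2, mat[map, map])
  cl2 <- chromosome_cluster(m2)
  part2 <- stats::cutree(cl2$hclust, k = 2)
  expect_true(part2[["chr1"]] == part2[["chr2"]])
  expect_false(part2[["chr1"]] == part2[["chr4"]])

  expect_error(chromosome_cluster(
    cm_from_dense(bin_genome(genome_spec("chr1", 5e5), 1e5),
                  matrix(1, 5, 5))), ">= 3 chromosomes")
})
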