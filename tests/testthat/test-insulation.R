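test_that("uniform matrices have zero normalized insulation", {
  n <- 40
  bins <- bins1(n, 5e4)
  m <- cm_from_dense(bins, matrix(3, n, n))
  tr <- insulation_score(m, w = 5)
  valid <- !is.na(tr$score)
  expect_equal(sum(valid), n - 2 * 5)
  expect_true(all(abs(tr$score[valid]) < 1e-12))
})

test_that("a two-block diagonal matrix has its score minimum at the junction", {
  n <- 40
  bins <- bins1(n, 5e4)
  mat <- matrix(0, n, n)
  mat[1:20, 1:20] <- 4
  mat[21:40, 21:40] <- 4
  mat <- mat + diag(n) * 0.1 + 0.2       # faint background keeps raw > 0
  m <- cm_from_dense(bins, mat)
  tr <- insulation_score(m, w = 5)
  # the junction lies between bins 20 and 21; both see the full
  # cross-block square, so the global minimum is one of the two
  expect_true(which.min(tr$score) %in% c(20, 21))
})

test_that("chromosomes shorter than the window give an all-NA track", {
  bins <- bins1(8, 5e4)
  m <- cm_from_dense(bins, matrix(2, 8, 8))
  tr <- insulation_score(m, w = 5)
  expect_true(all(is.na(tr$score)))
})

test_that("boundary calling finds valleys and honors the strength threshold", {
  n <- 60
  bins <- bins1(n, 5e4)
  mk_track <- function(score) {
    structure(data.frame(bins[c("chrom", "start", "end", "index")],
                         raw = 2^score, score = score,
                         stringsAsFactors = FALSE),
              resolution = 5e4, genome = attr(bins, "genome"), w = 5,
              class = c("insulation_track", "data.frame"))
  }
  # monotone: no boundary
  expect_equal(nrow(call_boundaries(mk_track(seq(0, 1, length.out = n)))), 0)

  # one sharp valley of depth 1 -> one boundary at the valley, strength 1
  s <- rep(0, n); s[30] <- -1
  b <- call_boundaries(mk_track(s), d = 2, threshold = 0.1)
  expect_equal(nrow(b), 1)
  expect_equal(b$bin, 29L)                # 0-based index of bin 30
  expect_equal(b$strength, 1)

  # two valleys, depths 0.05 and 0.5: only the deep one survives 0.1
  s2 <- rep(0, n); s2[15] <- -0.05; s2[40] <- -0.5
  b2 <- call_boundaries(mk_track(s2), d = 2, threshold = 0.1)
  expect_equal(b2$bin, 39L)
})

test_that("boundary comparison matches greedily within tolerance", {
  bins <- bins1(400, 5e4)
  a <- bset(bins, c(10, 50, 90))
  b <- bset(bins, c(11, 50, 300))
  cmp <- compare_boundaries(a, b, tolerance = 1)
  expect_equal(cmp$pairs$bin_a, c(50, 10))  # nearest-first: (50,50) then (10,11)
  expect_equal(cmp$pairs$bin_b, c(50, 11))
  expect_equal(cmp$specific_a$bin, 90)
  expect_equal(cmp$specific_b$bin, 300)

  # symmetry: swapping mirrors the specific sets
  cmp_rev <- compare_boundaries(b, a, tolerance = 1)
  expect_equal(cmp_rev$specific_a$bin, cmp$specific_b$bin)
  expect_equal(cmp_rev$specific_b$bin, cmp$specific_a$bin)

  # identical sets: nothing specific, nothing altered
  cmp_id <- compare_boundaries(a, a, tolerance = 1)
  expect_equal(nrow(cmp_id$specific_a), 0)
  at <- altered_tads(cmp_id, tads_from_boundaries(a))
  expect_false(any(at$tads$altered))
  expect_true(all(at$fractions == 0))

  # disjoint beyond tolerance: everything specific, all TADs altered
  cmp_dis <- compare_boundaries(bset(bins, c(100, 200)),
                                bset(bins, c(150, 250)), tolerance = 1)
  expect_equal(nrow(cmp_dis$pairs), 0)
  at_dis <- altered_tads(cmp_dis, tads_from_boundaries(bset(bins, c(100, 200))))
  expect_true(all(at_dis$tads$altered))
})

test_that("TADs tile between boundaries and sizes follow the bin arithmetic", {
  bins <- bins1(100, 5e4)
  tads <- tads_from_boundaries(bset(bins, c(20, 60)))
  expect_equal(nrow(tads), 3)
  expect_equal(sum(tads$size_bp), 100 * 5e4)
  # span [20, 60) in bins = 40 bins * 50 kb
  expect_equal(tads$size_bp[2], 40 * 5e4)
})

test_that("delta insulation and TAD size statistics", {
  n <- 40
  bins <- bins1(n, 5e4)
  m <- cm_from_dense(bins, matrix(3, n, n))
  tr <- insulation_score(m, w = 5)
  dd <- delta_insulation(tr, tr)
  expect_true(all(dd$delta_score[!is.na(dd$delta_score)] == 0))

  # rank-sum detects a 2x size shift with n = 30 per group
  set.seed(5)
  sizes <- c(rlnorm(30, log(6e5), 0.2), rlnorm(30, log(1.2e6), 0.2))
  tads <- structure(
    data.frame(chrom = "chr1", start = 0, end = sizes, size_bp = sizes,
               altered = rep(c(FALSE, TRUE), each = 30)),
    genome = attr(bins, "genome"), resolution = 5e4,
    class = c("tad_set", "data.frame"))
  st <- tad_size_stats(tads)
  expect_lt(st$test$p.value, 0.05)
  expect_gt(st$summary$median_bp[st$summary$group == "altered"],
            st$summary$median_bp[st$summary$group == "stable"])
})

test_that("planted boundaries are recovered from simulated matrices", {
  cfg <- synthetic_config(genome = genome_spec("chr1", 1e7),
                          resolutions = c(compartment = 5e5, tad = 5e4,
                                          trans = 5e5),
                          depth = 1e6, seed = 11, tad_enrichment = 3,
                          tad_gap_bins = c(12L, 20L),
                          n_loops_per_chrom = 0, translocations = NULL)
  pair <- generate_pair(cfg)
  truth_bins <- pair$truth$boundaries_normal$chr1 / 5e4
  m <- ice_normalize(pair$normal$tad)$matrix
  bs <- call_boundaries(insulation_score(m, w = 10), d = 2, threshold = 0.1)
  recall <- mean(vapply(truth_bins, function(b)
    min(abs(bs$bin - b)) <= 1, logical(1)))
  precision <- mean(vapply(bs$bin, function(cb)
    min(abs(truth_bins - cb)) <= 1, logical(1)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)

  # boundary count is stable under global matrix scaling
  m2 <- m; m2$mat <- m$mat * 2.5
  bs2 <- call_boundaries(insulation_score(m2, w = 10), d = 2, threshold = 0.1)
  expect_equal(bs2$bin, bs$bin)
})
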