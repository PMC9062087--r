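trans_fixture <- function(seed = 5, fold = 8) {
  cfg <- synthetic_config(
    genome = genome_spec(c("chr1", "chr2"), c(2e7, 1.6e7)),
    resolutions = c(compartment = 5e5, tad = 5e5, trans = 4e4),
    depth = 3e6, seed = seed, n_loops_per_chrom = 0,
    translocations = data.frame(chrom_a = "chr1", start_a = 8e6,
                                chrom_b = "chr2", start_b = 4e6,
                                span_a_bins = 30L, span_b_bins = 20L,
                                fold = fold))
  generate_pair(cfg)
}

test_that("uniform trans background yields no candidates", {
  g <- genome_spec(c("chr1", "chr2"), c(4e6, 4e6))
  bins <- bin_genome(g, 1e5)
  n <- nrow(bins)
  mat <- matrix(0, n, n)
  mat[1:40, 41:80] <- 2
  mat[41:80, 1:40] <- 2
  m <- cm_from_dense(bins, mat)
  expect_equal(nrow(trans_hotspot_scan(m, fold = 4, min_span = 5)), 0)
  # all-zero matrix: empty result
  empty <- contact_matrix(bins, kind = "normalized")
  expect_equal(nrow(trans_hotspot_scan(empty)), 0)
})

test_that("a planted block is recovered with tight edges and then masked", {
  pair <- trans_fixture(seed = 5)
  mt <- ice_normalize(pair$tumor$trans)$matrix
  ev <- trans_hotspot_scan(mt, fold = 4, min_span = 5)
  expect_equal(nrow(ev), 1)
  expect_lte(max(abs(c(ev$start_a - 8e6, ev$end_a - 9.2e6,
                       ev$start_b - 4e6, ev$end_b - 4.8e6))) / 4e4, 1)
  expect_gt(ev$fold_enrichment, 4)

  # determinism: identical input, identical events
  expect_identical(as.data.frame(trans_hotspot_scan(mt, fold = 4,
                                                    min_span = 5)),
                   as.data.frame(ev))

  # the normal sample has no hotspot
  mn <- ice_normalize(pair$normal$trans)$matrix
  expect_equal(nrow(trans_hotspot_scan(mn, fold = 4, min_span = 5)), 0)

  # confirmation requires a breakpoint at an edge
  bp_at_edge <- structure(
    data.frame(chromA = "chr1", posA = 8.01e6, chromB = "chr2", posB = 1e6),
    class = c("breakpoint_set", "data.frame"))
  conf <- double_confirm(ev, bp_at_edge, tolerance = 1)
  expect_equal(conf$status, "double-confirmed")
  expect_equal(conf$n_support, 1L)

  bp_far <- structure(
    data.frame(chromA = "chr1", posA = 8e6 + 5 * 4e4,
               chromB = "chr2", posB = 4e6 + 5 * 4e4),
    class = c("breakpoint_set", "data.frame"))
  expect_equal(double_confirm(ev, bp_far, tolerance = 1)$status, "candidate")
  # monotone in tolerance: a wide enough edge window recovers it
  expect_equal(double_confirm(ev, bp_far, tolerance = 5)$status,
               "double-confirmed")
  # no breakpoints at all: nothing confirmed
  expect_equal(double_confirm(ev, NULL)$status, "candidate")

  # masking removes the block: rescan is empty, cis untouched,
  # trans total drops by exactly the in-block sum
  masked <- mask_events(mt, conf)
  expect_equal(nrow(trans_hotspot_scan(masked, fold = 4, min_span = 5)), 0)
  before <- cis_trans_ratio(mt); after <- cis_trans_ratio(masked)
  expect_equal(after$cis, before$cis)
  blk <- cm_block(mt, "chr1", "chr2")
  ra <- ev$start_a / 4e4 + seq_len((ev$end_a - ev$start_a) / 4e4)
  rb <- ev$start_b / 4e4 + seq_len((ev$end_b - ev$start_b) / 4e4)
  expect_equal(before$trans - after$trans, sum(blk[ra, rb]))
})

test_that("two disjoint planted blocks give two unmerged events", {
  cfg <- synthetic_config(
    genome = genome_spec(c("chr1", "chr2"), c(2e7, 1.6e7)),
    resolutions = c(compartment = 5e5, tad = 5e5, trans = 4e4),
    depth = 3e6, seed = 8, n_loops_per_chrom = 0,
    translocations = data.frame(chrom_a = c("chr1", "chr1"),
                                start_a = c(4e6, 14e6),
                                chrom_b = c("chr2", "chr2"),
                                start_b = c(2e6, 10e6),
                                span_a_bins = c(25L, 20L),
                                span_b_bins = c(20L, 25L),
                                fold = c(8, 8)))
  pair <- generate_pair(cfg)
  mt <- ice_normalize(pair$tumor$trans)$matrix
  ev <- trans_hotspot_scan(mt, fold = 4, min_span = 5)
  expect_equal(nrow(ev), 2)
  ev <- ev[order(ev$start_a), ]
  expect_lte(abs(ev$start_a[1] - 4e6) / 4e4, 1)
  expect_lte(abs(ev$start_a[2] - 14e6) / 4e4, 1)
})

test_that("SV overlap enrichment fractions and chi-square", {
  # 100 boundary features, 20 altered; SVs hit 10 features, 8 of them altered
  feats <- data.frame(chrom = "chr1", start = seq(0, 99) * 1e5,
                      end = seq(0, 99) * 1e5 + 5e4)
  altered <- rep(FALSE, 100); altered[1:20] <- TRUE
  hit_idx <- c(1:8, 50, 60)
  svs <- structure(
    data.frame(chrom = "chr1", start = feats$start[hit_idx] + 1e4,
               end = feats$start[hit_idx] + 2e4, type = "deletion"),
    class = c("sv_set", "data.frame"))
  out <- sv_overlap_enrichment(feats, altered, svs)
  expect_equal(out$frac_all, 0.10)
  expect_equal(out$frac_altered, 0.40)
  oracle <- chisq_oracle(rbind(c(8, 12), c(2, 78)))
  expect_equal(out$chisq, oracle$statistic, tolerance = 1e-9)
  expect_equal(out$p, oracle$p.value, tolerance = 1e-9)

  # no SVs of a type: both fractions zero
  out0 <- sv_overlap_enrichment(feats, altered, svs[0, ], types = "inversion")
  expect_equal(out0$frac_all, 0)
  expect_equal(out0$frac_altered, 0)

  # SVs covering the whole genome: both fractions 1, chi-square 0
  sv_all <- structure(
    data.frame(chrom = "chr1", start = 0, end = 1e7, type = "duplication"),
    class = c("sv_set", "data.frame"))
  out1 <- sv_overlap_enrichment(feats, altered, sv_all)
  expect_equal(out1$frac_all, 1)
  expect_equal(out1$frac_altered, 1)
  expect_equal(out1$chisq, 0)
  expect_error(sv_overlap_enrichment(feats[0, ], logical(0), svs), "empty")
})

test_that("fold-4 blocks spanning 10+ bins are recovered across 20 seeds", {
  ok <- 0L
  for (seed in 1:20) {
    cfg <- synthetic_config(
      genome = genome_spec(c("chr1", "chr2"), c(2e7, 1.6e7)),
      resolutions = c(compartment = 5e5, tad = 5e5, trans = 4e4),
      depth = 1e7, seed = 200 + seed, n_loops_per_chrom = 0,
      translocations = data.frame(chrom_a = "chr1", start_a = 8e6,
                                  chrom_b = "chr2", start_b = 4e6,
                                  span_a_bins = 15L, span_b_bins = 12L,
                                  fold = 4))
    pair <- generate_pair(cfg)
    ev <- trans_hotspot_scan(ice_normalize(pair$tumor$trans)$matrix,
                             fold = 3, min_span = 5)
    if (nrow(ev) == 1) {
      err <- max(abs(c(ev$start_a - 8e6, ev$end_a - (8e6 + 15 * 4e4),
                       ev$start_b - 4e6, ev$end_b - (4e6 + 12 * 4e4)))) / 4e4
      if (err <= 1) ok <- ok + 1L
    }
  }
  expect_gte(ok / 20, 0.95)
})
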