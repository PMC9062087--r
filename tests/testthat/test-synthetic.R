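test_that("pure power-law decay is generated when structure is off", {
  cfg <- synthetic_config(genome = genome_spec("chr1", 3e7),  # 600 bins
                          resolutions = c(compartment = 5e5, tad = 5e4,
                                          trans = 5e5),
                          depth = 2e6, seed = 3, plaid_k = 1,
                          tad_enrichment = 1, n_loops_per_chrom = 0,
                          translocations = NULL)
  pair <- generate_pair(cfg)
  m <- ice_normalize(pair$normal$tad)$matrix
  dc <- decay_curve(m)
  fit <- dc$segments$exponent[dc$segments$name == "0.1-1Mb"]
  expect_lt(abs(fit - cfg$alpha), 0.1)
})

test_that("generation is deterministic and conserves depth", {
  cfg <- synthetic_config(genome = genome_spec(c("chr1", "chr2"), c(8e6, 6e6)),
                          resolutions = c(compartment = 5e5, tad = 2e5,
                                          trans = 2e5),
                          depth = 5e5, seed = 31,
                          boundary_altered_fraction = 0.4,
                          translocations = NULL)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- generate_pair(cfg)
  g1 <- generate_expression(p1$truth, seed = 4, n_per_class = 50)
  emit_files(p1, d1, genes = g1)
  p2 <- generate_pair(cfg)
  g2 <- generate_expression(p2$truth, seed = 4, n_per_class = 50)
  emit_files(p2, d2, genes = g2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "manifest.json"))   # manifest embeds absolute paths
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  md1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  md2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(md1$md5, md2$md5)

  # total counts within 3 sigma of the configured depth (Poisson)
  for (nm in names(p1$normal)) {
    tot <- sum(hicpair:::cm_triplets(p1$normal[[nm]])$x)
    expect_lt(abs(tot - cfg$depth), 3 * sqrt(cfg$depth))
  }

  # truth JSON round-trips
  tr <- read_truth(file.path(d1, "truth.json"))
  expect_equal(tr$compartment$class, p1$truth$compartment$class)
  expect_equal(tr$boundaries_normal$chr1, p1$truth$boundaries_normal$chr1)
  expect_equal(tr$seed, cfg$seed)
})

test_that("the tumor differs from normal only by configured alterations", {
  cfg <- synthetic_config(genome = genome_spec(c("chr1", "chr2"), c(2e7, 1.6e7)),
                          resolutions = c(compartment = 5e5, tad = 5e4,
                                          trans = 2e5),
                          depth = 2e6, seed = 19)
  pair <- generate_pair(cfg)
  tr <- pair$truth
  # planted switch fractions close to the configured targets
  w <- tr$compartment$end - tr$compartment$start
  fr_b2a <- sum(w[tr$compartment$class == "B2A"]) / sum(w)
  fr_a2b <- sum(w[tr$compartment$class == "A2B"]) / sum(w)
  # granularity: whole blocks flip, so the realized fraction can sit up to
  # about one block length (~4 Mb of 36 Mb here) from the target
  expect_lt(abs(fr_b2a - cfg$b2a_fraction), 0.12)
  expect_lt(abs(fr_a2b - cfg$a2b_fraction), 0.07)

  # translocation raises the tumor trans fraction
  tf_n <- cis_trans_ratio(pair$normal$trans)$trans_fraction
  tf_t <- cis_trans_ratio(pair$tumor$trans)$trans_fraction
  expect_gt(tf_t, tf_n)

  # planted trans block enrichment: divide out the known bias vector and
  # compare the block mean with the background mean on the same scale
  blk <- cm_block(pair$tumor$trans, "chr1", "chr2")
  bias <- tr$bias$tumor$trans
  bins <- pair$tumor$trans$bins
  bA <- bias[bins$chrom == "chr1"]; bB <- bias[bins$chrom == "chr2"]
  blk_c <- blk / outer(bA, bB)
  tl <- cfg$translocations
  res_tr <- cfg$resolutions[["trans"]]
  ra <- (tl$start_a / res_tr) + seq_len(tl$span_a_bins)
  rb <- (tl$start_b / res_tr) + seq_len(tl$span_b_bins)
  fold_hat <- mean(blk_c[ra, rb]) / mean(blk_c[-ra, -rb])
  expect_gte(fold_hat, 6)
  expect_lte(fold_hat, 10)

  # planted loop dots are enriched over same-distance background (O/E)
  lp <- tr$loops_normal[tr$loops_normal$chrom == "chr1", ][1:8, ]
  oe <- observed_over_expected(ice_normalize(pair$normal$tad)$matrix)
  ctad <- cm_block(oe, "chr1")
  res <- 5e4
  hits <- vapply(seq_len(nrow(lp)), function(k) {
    i <- floor((lp$start1[k] + lp$end1[k]) / 2 / res) + 1
    j <- floor((lp$start2[k] + lp$end2[k]) / 2 / res) + 1
    ctad[i, j] > 1
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("translocation spans beyond the chromosome are rejected", {
  expect_error(
    synthetic_config(genome = genome_spec(c("chr1", "chr2"), c(2e6, 2e6)),
                     translocations = data.frame(
                       chrom_a = "chr1", start_a = 1.9e6, chrom_b = "chr2",
                       start_b = 0, span_a_bins = 30L, span_b_bins = 5L,
                       fold = 8)),
    "exceeds chromosome")
})

test_that("expression effects follow the planted classes", {
  cfg <- synthetic_config(genome = genome_spec(c("chr1", "chr2"), c(2e7, 1.6e7)),
                          resolutions = c(compartment = 5e5, tad = 2e5,
                                          trans = 2e5),
                          depth = 5e5, seed = 23)
  pair <- generate_pair(cfg)
  genes <- generate_expression(pair$truth, b2a_shift = 2, sigma = 0.5,
                               n_per_class = 300, seed = 7)
  b2a <- genes[genes$class == "B2A", ]
  expect_gt(sum(b2a$status == "up") / sum(b2a$status == "down"), 1)
  a2b <- genes[genes$class == "A2B", ]
  expect_lt(sum(a2b$status == "up") / max(sum(a2b$status == "down"), 1), 1)
  stable <- genes[genes$class == "stable", ]
  expect_lt(abs(stats::median(stable$log2FC)), 0.1)

  # null effects: DE fraction stays near the thresholds' false-positive rate
  null_genes <- generate_expression(pair$truth, b2a_shift = 0, a2b_shift = 0,
                                    tad_effect = 0, loop_effect = 0,
                                    sigma = 0.5, n_per_class = 300, seed = 8)
  expect_lt(mean(null_genes$status != "not-DE"), 0.1)

  # over-capacity requests fail loudly
  expect_error(generate_expression(pair$truth, n_per_class = 1e6),
               "capacity")
})
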