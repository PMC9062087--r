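# half-maximum edge localization on a 1-d enrichment profile: starting from
# the anchor, expand in both directions while the profile stays above the
# midpoint between baseline and plateau, tolerating single-bin dropouts;
# returns c(lo, hi) in profile coordinates, or NULL if no plateau
profile_edges <- function(prof, anchor, span_lo, span_hi, smooth = 1L) {
  if (smooth > 1) {
    # symmetric running mean: unbiased for a step edge, damps sparse noise
    k <- as.integer(smooth) - (1L - as.integer(smooth) %% 2L)  # odd <= smooth
    if (k > 1) {
      n <- length(prof)
      cs <- cumsum(c(0, prof))
      h <- k %/% 2
      lo_i <- pmax(seq_len(n) - h, 1L); hi_i <- pmin(seq_len(n) + h, n)
      prof <- (cs[hi_i + 1] - cs[lo_i]) / (hi_i - lo_i + 1)
    }
  }
  base <- stats::median(prof)
  plateau <- stats::quantile(prof[span_lo:span_hi], 0.9, names = FALSE)
  if (plateau <= base) return(NULL)
  level <- base + (plateau - base) / 2
  above <- prof >= level
  if (!above[anchor]) {
    near <- which(above[span_lo:span_hi]) + span_lo - 1L
    if (!length(near)) return(NULL)
    anchor <- near[which.min(abs(near - anchor))]
  }
  lo <- anchor
  while (lo > 1 && (above[lo - 1] || (lo > 2 && above[lo - 2])))
    lo <- lo - 1L
  if (!above[lo]) lo <- lo + 1L
  hi <- anchor
  n <- length(prof)
  while (hi < n && (above[hi + 1] || (hi < n - 1 && above[hi + 2])))
    hi <- hi + 1L
  if (!above[hi]) hi <- hi - 1L
  c(lo, hi)
}

# mean of norm over s x s windows (integral image); result dims (n-s+1, m-s+1)
box_means <- function(norm, s) {
  n <- nrow(norm); m <- ncol(norm)
  cs <- rbind(0, apply(norm, 2, cumsum))
  cs <- cbind(0, t(apply(cs, 1, cumsum)))
  (cs[(s + 1):(n + 1), (s + 1):(m + 1), drop = FALSE] -
     cs[1:(n - s + 1), (s + 1):(m + 1), drop = FALSE] -
     cs[(s + 1):(n + 1), 1:(m - s + 1), drop = FALSE] +
     cs[1:(n - s + 1), 1:(m - s + 1), drop = FALSE]) / s^2
}

scan_block <- function(blk, background, fold, min_span) {
  # entry-level enrichment over the expected row x column marginal product:
  # removes per-bin trends (bias, compartment coupling). A hotspot inflates
  # its own marginals — on a small matrix enough to hide itself — so a
  # second pass recomputes the expectation with mildly enriched regions
  # peeled out before seeding.
  s <- max(2L, as.integer(min_span))
  if (nrow(blk) < s || ncol(blk) < s) return(NULL)
  expectation <- function(src) {
    rm_ <- rowMeans(src); cm_ <- colMeans(src); gm <- mean(src)
    if (gm <= 0) return(matrix(0, nrow(src), ncol(src)))
    outer(rm_, cm_) / gm
  }
  ex1 <- expectation(blk)
  norm1 <- ifelse(ex1 > 0, blk / ex1, 0)
  bm1 <- box_means(norm1, s)
  # peel the top box quantile: a hotspot occupying a sizable share of a
  # small matrix absorbs into its own marginals, so the peel must not
  # depend on it already standing far above the noise. Peeled entries are
  # replaced by their first-pass expectation (not dropped) so sparse rows
  # keep a stable marginal estimate.
  peel_thr <- max(stats::quantile(bm1, 0.95), 1)
  hot <- which(bm1 >= peel_thr, arr.ind = TRUE)
  excl <- matrix(FALSE, nrow(blk), ncol(blk))
  for (di in 0:(s - 1)) for (dj in 0:(s - 1))
    excl[hot + rep(c(di, dj), each = nrow(hot))] <- TRUE
  capped <- blk
  capped[excl] <- pmin(blk[excl], ex1[excl])
  ex2 <- expectation(capped)
  norm <- ifelse(ex2 > 0, blk / ex2, 0)
  bm <- box_means(norm, s)
  seed_thr <- max(fold / 2, stats::median(bm) + 5 * stats::mad(bm))
  seeds <- which(bm >= seed_thr, arr.ind = TRUE)
  if (!nrow(seeds)) return(NULL)
  if (nrow(seeds) > 3000) {
    keep <- order(bm[seeds], decreasing = TRUE)[1:3000]
    seeds <- seeds[keep, , drop = FALSE]
  }
  # group seeds whose windows touch (single-linkage on window distance)
  grp <- seq_len(nrow(seeds))
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(seeds))) {
      near <- abs(seeds[, 1] - seeds[k, 1]) <= s &
        abs(seeds[, 2] - seeds[k, 2]) <= s
      g <- min(grp[near])
      if (any(grp[near] != g)) { grp[grp %in% grp[near]] <- g; changed <- TRUE }
    }
    if (!changed) break
  }
  refine <- function(profile, anchor, lo, hi) {
    e <- profile_edges(profile, anchor, lo, hi, smooth = 3L)
    if (is.null(e)) c(lo, hi) else e
  }
  # isolated noise boxes do not form the dense seed cluster a real block
  # (span >= min_span in both dimensions) produces
  gmin <- max(4, as.integer(((min_span + 1) / 2)^2))
  cands <- list()
  for (g in unique(grp)) {
    sel <- seeds[grp == g, , drop = FALSE]
    if (nrow(sel) < gmin) next
    peak <- sel[which.max(bm[sel]), ]
    r0 <- peak[1] + s %/% 2; c0 <- peak[2] + s %/% 2
    # initial span: the seed cluster's bounding box — wide enough that the
    # restricted profiles average over most of the hotspot
    r_lo <- min(sel[, 1]); r_hi <- max(sel[, 1]) + s - 1L
    c_lo <- min(sel[, 2]); c_hi <- max(sel[, 2]) + s - 1L
    # grow edges from the peak on profiles restricted to the other span
    for (pass in 1:2) {
      rs <- refine(rowMeans(norm[, c_lo:c_hi, drop = FALSE]), r0, r_lo, r_hi)
      r_lo <- rs[1]; r_hi <- rs[2]
      cs2 <- refine(colMeans(norm[r_lo:r_hi, , drop = FALSE]), c0, c_lo, c_hi)
      c_lo <- cs2[1]; c_hi <- cs2[2]
    }
    if (r_hi - r_lo + 1 < min_span || c_hi - c_lo + 1 < min_span) next
    # a refined block must itself be enriched, not just contain hot boxes
    if (mean(norm[r_lo:r_hi, c_lo:c_hi]) < fold / 2) next
    cands[[length(cands) + 1]] <- data.frame(
      r_lo = unname(r_lo), r_hi = unname(r_hi), c_lo = unname(c_lo),
      c_hi = unname(c_hi), mean = mean(blk[r_lo:r_hi, c_lo:c_hi]))
  }
  if (!length(cands)) return(NULL)
  cands <- do.call(rbind, cands)
  # merge overlapping candidate blocks (union of spans)
  repeat {
    merged <- FALSE
    if (nrow(cands) >= 2) {
      for (i in 1:(nrow(cands) - 1)) {
        for (j in (i + 1):nrow(cands)) {
          if (cands$r_lo[i] <= cands$r_hi[j] && cands$r_lo[j] <= cands$r_hi[i] &&
              cands$c_lo[i] <= cands$c_hi[j] && cands$c_lo[j] <= cands$c_hi[i]) {
            cands$r_lo[i] <- min(cands$r_lo[i], cands$r_lo[j])
            cands$r_hi[i] <- max(cands$r_hi[i], cands$r_hi[j])
            cands$c_lo[i] <- min(cands$c_lo[i], cands$c_lo[j])
            cands$c_hi[i] <- max(cands$c_hi[i], cands$c_hi[j])
            cands <- cands[-j, , drop = FALSE]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  for (k in seq_len(nrow(cands)))
    cands$mean[k] <- mean(blk[cands$r_lo[k]:cands$r_hi[k],
                              cands$c_lo[k]:cands$c_hi[k]])
  cands
}

#' Scan trans blocks for translocation hotspots
#'
#' For each chromosome pair, computes entry-level enrichment over the
#' expected row-by-column marginal product (removing per-bin trends), seeds
#' candidate regions where box-filtered enrichment stands above both half
#' the fold threshold and the box-level noise, and localizes each
#' candidate's edges by half-maximum crossings of the span-restricted
#' row-mean and column-mean profiles. A candidate is kept iff its block
#' mean is at least `fold` times the background and both spans reach
#' `min_span` bins; overlapping candidates are merged. The background is
#' the mean trans entry of the pair's block, recomputed with candidate
#' blocks excluded so a hotspot does not inflate its own reference level.
#' Best run on an ICE-normalized matrix (bias distorts raw profiles).
#'
#' @param m A genome-wide [contact_matrix()] at translocation resolution.
#' @param fold Fold-over-background detection threshold (default 4).
#' @param min_span Minimum span in bins on each chromosome (default 5).
#' @return A `translocation_set`: data.frame with bp spans on both
#'   chromosomes, `mean_signal`, `background`, `fold_enrichment` and
#'   `status` (`"candidate"`).
#' @export
trans_hotspot_scan <- function(m, fold = 4, min_span = 5) {
  bins <- m$bins
  res <- attr(bins, "resolution")
  genome <- attr(bins, "genome")
  chroms <- names(genome)
  events <- list()
  for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
    if (b <= a) next
    keep_a <- which(!cm_block_mask(m, chroms[a]))
    keep_b <- which(!cm_block_mask(m, chroms[b]))
    if (length(keep_a) < min_span || length(keep_b) < min_span) next
    blk <- cm_block(m, chroms[a], chroms[b])[keep_a, keep_b, drop = FALSE]
    if (!any(blk > 0)) next
    background <- mean(blk)
    cands <- scan_block(blk, background, fold, min_span)
    if (is.null(cands)) next
    # background excluding detected blocks (robust to the hotspots themselves)
    out_mask <- matrix(TRUE, nrow(blk), ncol(blk))
    for (k in seq_len(nrow(cands)))
      out_mask[cands$r_lo[k]:cands$r_hi[k], cands$c_lo[k]:cands$c_hi[k]] <- FALSE
    if (any(out_mask)) background <- mean(blk[out_mask])
    cands <- cands[cands$mean >= fold * background, , drop = FALSE]
    if (!nrow(cands)) next
    # map kept-space spans back to original bin indices
    cands$r_lo <- keep_a[cands$r_lo]; cands$r_hi <- keep_a[cands$r_hi]
    cands$c_lo <- keep_b[cands$c_lo]; cands$c_hi <- keep_b[cands$c_hi]
    sa <- bins$start[bins$chrom == chroms[a]]
    sb <- bins$start[bins$chrom == chroms[b]]
    ea <- bins$end[bins$chrom == chroms[a]]
    eb <- bins$end[bins$chrom == chroms[b]]
    for (k in seq_len(nrow(cands))) {
      events[[length(events) + 1]] <- data.frame(
        chrom_a = chroms[a], start_a = sa[cands$r_lo[k]],
        end_a = ea[cands$r_hi[k]],
        chrom_b = chroms[b], start_b = sb[cands$c_lo[k]],
        end_b = eb[cands$c_hi[k]],
        mean_signal = cands$mean[k], background = background,
        fold_enrichment = cands$mean[k] / background,
        status = "candidate", stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom_a = character(), start_a = numeric(), end_a = numeric(),
               chrom_b = character(), start_b = numeric(), end_b = numeric(),
               mean_signal = numeric(), background = numeric(),
               fold_enrichment = numeric(), status = character(),
               stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  structure(ev, resolution = res, genome = genome,
            class = c("translocation_set", "data.frame"))
}

#' Double-confirm translocation candidates with WGS breakpoints
#'
#' A candidate is confirmed iff at least one of its four span edges
#' (start/end bin on either chromosome), widened by `tolerance` bins on each
#' side, contains the corresponding-chromosome position of some breakpoint
#' on the same chromosome pair (either orientation).
#'
#' @param events A `translocation_set` from [trans_hotspot_scan()].
#' @param breakpoints A `breakpoint_set`.
#' @param tolerance Edge widening in bins (default 1).
#' @return The events with `status` set to `"double-confirmed"` where
#'   supported and a `n_support` column of supporting breakpoint counts.
#' @export
double_confirm <- function(events, breakpoints, tolerance = 1) {
  res <- attr(events, "resolution")
  pad <- tolerance * res
  events$n_support <- rep(0L, nrow(events))
  if (!nrow(events) || is.null(breakpoints) || !nrow(breakpoints))
    return(events)
  edge_hit <- function(pos, span_start, span_end) {
    # edge bins of the span, widened +/- pad
    (pos >= span_start - pad & pos < span_start + res + pad) |
      (pos >= span_end - res - pad & pos < span_end + pad)
  }
  for (k in seq_len(nrow(events))) {
    for (r in seq_len(nrow(breakpoints))) {
      bp <- breakpoints[r, ]
      if (bp$chromA == events$chrom_a[k] && bp$chromB == events$chrom_b[k]) {
        pa <- bp$posA; pb <- bp$posB
      } else if (bp$chromA == events$chrom_b[k] &&
                 bp$chromB == events$chrom_a[k]) {
        pa <- bp$posB; pb <- bp$posA
      } else next
      hit <- edge_hit(pa, events$start_a[k], events$end_a[k]) ||
        edge_hit(pb, events$start_b[k], events$end_b[k])
      if (hit) events$n_support[k] <- events$n_support[k] + 1L
    }
    if (events$n_support[k] > 0) events$status[k] <- "double-confirmed"
  }
  events
}

#' Mask confirmed translocation blocks out of a matrix
#'
#' Zeroes every entry falling inside a confirmed event's chromosome-pair
#' block (both storage orientations) and records the block so downstream
#' operations see the mask. Cis entries are never touched.
#'
#' @param m A [contact_matrix()].
#' @param events A `translocation_set`; only rows with status
#'   `"double-confirmed"` are masked.
#' @return The masked `contact_matrix` (masked blocks recorded in
#'   `$masked_blocks`).
#' @export
mask_events <- function(m, events) {
  conf <- events[events$status == "double-confirmed", , drop = FALSE]
  if (!nrow(conf)) return(m)
  bins <- m$bins
  t3 <- methods::as(m$mat, "TsparseMatrix")
  ii <- t3@i + 1L; jj <- t3@j + 1L
  drop <- rep(FALSE, length(ii))
  blocks <- m$masked_blocks
  for (k in seq_len(nrow(conf))) {
    ra <- which(bins$chrom == conf$chrom_a[k] & bins$start >= conf$start_a[k] &
                  bins$end <= conf$end_a[k])
    rb <- which(bins$chrom == conf$chrom_b[k] & bins$start >= conf$start_b[k] &
                  bins$end <= conf$end_b[k])
    drop <- drop | (ii %in% ra & jj %in% rb) | (ii %in% rb & jj %in% ra)
    blocks[[length(blocks) + 1]] <- conf[k, c("chrom_a", "start_a", "end_a",
                                              "chrom_b", "start_b", "end_b")]
  }
  mat <- Matrix::sparseMatrix(i = ii[!drop], j = jj[!drop], x = t3@x[!drop],
                              dims = dim(m$mat))
  new_contact_matrix(bins, mat, m$kind, m$mask, blocks)
}

#' Structural-variant overlap enrichment for boundaries or anchors
#'
#' For each SV type, a feature is "affected" iff its interval overlaps any
#' SV of that type (>= 1 bp). Reports the affected fraction among all
#' features and among the altered subset, with a Pearson chi-square test
#' (no continuity correction) on the 2x2 table altered-status x affected.
#'
#' @param features Data frame with `chrom`, `start`, `end` (boundary bins or
#'   loop anchors).
#' @param altered Logical vector flagging the altered (condition-specific)
#'   subset of `features`.
#' @param svs A `sv_set`.
#' @param types SV types to report (default: those present in `svs`).
#' @return Data frame per type: `frac_all`, `frac_altered`, `chisq`, `p`.
#' @export
sv_overlap_enrichment <- function(features, altered, svs,
                                  types = unique(svs$type)) {
  if (!nrow(features)) stop("empty feature set")
  stopifnot(length(altered) == nrow(features))
  fr <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(features$start + 1,
                                                features$end))
  out <- lapply(types, function(ty) {
    sv <- svs[svs$type == ty, , drop = FALSE]
    hit <- if (nrow(sv)) IRanges::overlapsAny(
      fr, GenomicRanges::GRanges(sv$chrom,
                                 IRanges::IRanges(sv$start + 1, sv$end)))
    else rep(FALSE, nrow(features))
    tab <- rbind(altered = c(sum(hit & altered), sum(!hit & altered)),
                 other = c(sum(hit & !altered), sum(!hit & !altered)))
    ct <- contingency_chisq(tab)
    data.frame(type = ty, n_sv = nrow(sv),
               frac_all = mean(hit),
               frac_altered = if (any(altered)) mean(hit[altered]) else NA_real_,
               chisq = ct$statistic, p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
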