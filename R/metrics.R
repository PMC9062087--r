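#' Expected contact by genomic distance for one chromosome
#'
#' `E(d)` is the mean value over all unmasked bin pairs of the chromosome at
#' bin distance `d` (zeros included in the mean; masked bins excluded from
#' both numerator and denominator).
#'
#' @param m A cis-containing [contact_matrix()].
#' @param chrom Chromosome name.
#' @return Numeric vector of length `nbins`, `E(d)` for `d = 0..nbins-1`;
#'   `NA` where no unmasked pair exists.
#' @export
expected_by_distance <- function(m, chrom) {
  st <- distance_sums(m, chrom)
  ifelse(st$pairs > 0, st$sums / st$pairs, NA_real_)
}

# per-distance sums and unmasked pair counts for one chromosome's cis block
distance_sums <- function(m, chrom) {
  b <- cm_block(m, chrom)
  keep <- !cm_block_mask(m, chrom)
  n <- nrow(b)
  if (!any(keep)) return(list(sums = numeric(n), pairs = numeric(n)))
  b <- b[keep, keep, drop = FALSE]
  loc <- which(keep)
  d <- abs(outer(loc, loc, "-"))
  ut <- upper.tri(d, diag = TRUE)
  sums <- pairs <- numeric(n)
  agg_s <- tapply(b[ut], d[ut], sum)
  agg_n <- tapply(rep(1, sum(ut)), d[ut], sum)
  at <- as.integer(names(agg_s)) + 1L
  sums[at] <- as.numeric(agg_s)
  pairs[at] <- as.numeric(agg_n)
  list(sums = sums, pairs = pairs)
}

#' Observed/expected transformation of cis blocks
#'
#' Divides every cis entry by the chromosome's expected value at its bin
#' distance. Entries where the expected value is zero or undefined, and all
#' trans entries, are dropped (observed/expected is a cis-only concept here).
#'
#' @param m A normalized [contact_matrix()].
#' @return A `contact_matrix` of O/E values.
#' @export
observed_over_expected <- function(m) {
  if (Matrix::nnzero(m$mat) == 0) stop("empty matrix")
  bins <- m$bins
  offs <- chrom_offsets(bins)
  trip_i <- integer(); trip_j <- integer(); trip_x <- numeric()
  for (ch in names(attr(bins, "genome"))) {
    e <- expected_by_distance(m, ch)
    b <- cm_block(m, ch)
    keep <- !cm_block_mask(m, ch)
    n <- nrow(b)
    idx <- which(upper.tri(b, diag = TRUE), arr.ind = TRUE)
    d <- idx[, 2] - idx[, 1]
    ok <- keep[idx[, 1]] & keep[idx[, 2]] & !is.na(e[d + 1]) & e[d + 1] > 0
    idx <- idx[ok, , drop = FALSE]; d <- d[ok]
    oe <- b[idx] / e[d + 1]
    nz <- oe != 0
    trip_i <- c(trip_i, offs[ch] + idx[nz, 1] - 1L)
    trip_j <- c(trip_j, offs[ch] + idx[nz, 2] - 1L)
    trip_x <- c(trip_x, oe[nz])
  }
  contact_matrix(bins, i = trip_i, j = trip_j, x = trip_x,
                 kind = "normalized", mask = m$mask)
}

#' Cis/trans interaction balance
#'
#' @param m A genome-wide [contact_matrix()] (cis and trans together).
#' @return List with `cis`, `trans` totals (upper triangle, diagonal once)
#'   and `trans_fraction` = trans / (cis + trans).
#' @export
cis_trans_ratio <- function(m) {
  tot <- cm_cis_trans_totals(m)
  denom <- sum(tot)
  list(cis = unname(tot["cis"]), trans = unname(tot["trans"]),
       trans_fraction = if (denom > 0) unname(tot["trans"]) / denom else NA_real_)
}

default_ide_segments <- function() {
  data.frame(name = c("0.1-1Mb", "1-10Mb", "10Mb+"),
             lo = c(1e5, 1e6, 1e7), hi = c(1e6, 1e7, Inf),
             stringsAsFactors = FALSE)
}

#' Distance-decay curve and segmented decay exponents
#'
#' Pools per-distance mean contact across chromosomes, summarizes it in
#' log-spaced distance bins (geometric means, 16 bins per decade by default)
#' and fits an ordinary least-squares line in log10-log10 space within each
#' distance segment, giving the per-segment distance decay exponent. The
#' default segments are (0.1-1 Mb], (1-10 Mb] and (10 Mb, Inf); a segment
#' needs at least 3 populated distance bins, otherwise its exponent is
#' flagged undefined. Fitting uses the mean (not the sum) of contact per
#' distance, so pair-count differences between distances do not bias the
#' slope; within a log bin both axes are averaged in log space, which makes
#' the fit exact on an exact power law.
#'
#' @param m A normalized [contact_matrix()].
#' @param segments Data frame with columns `name`, `lo`, `hi` (bp,
#'   half-open `(lo, hi]`).
#' @param bins_per_decade Log-spaced distance bins per decade (default 16).
#' @return A `decay_curve`: list with `curve` (data.frame of distance bin,
#'   geometric-mean distance and contact) and `segments` (data.frame with
#'   fitted `exponent`, `intercept`, `n_points`, `ok`).
#' @export
decay_curve <- function(m, segments = default_ide_segments(),
                        bins_per_decade = 16) {
  res <- attr(m$bins, "resolution")
  genome <- attr(m$bins, "genome")
  nmax <- max(chrom_nbins(m$bins))
  sums <- pairs <- numeric(nmax)
  for (ch in names(genome)) {
    st <- distance_sums(m, ch)
    k <- length(st$sums)
    sums[1:k] <- sums[1:k] + st$sums
    pairs[1:k] <- pairs[1:k] + st$pairs
  }
  d <- which(pairs > 0 & sums > 0) - 1L     # bin distances with signal
  d <- d[d >= 1]                            # diagonal excluded from decay
  if (!length(d)) stop("no nonzero off-diagonal cis signal")
  ed <- sums[d + 1] / pairs[d + 1]
  dist_bp <- d * res
  lg <- log10(dist_bp)
  edges <- seq(floor(min(lg) * bins_per_decade) / bins_per_decade,
               ceiling(max(lg) * bins_per_decade) / bins_per_decade +
                 1 / bins_per_decade,
               by = 1 / bins_per_decade)
  grp <- cut(lg, edges, include.lowest = TRUE)
  gx <- tapply(lg, grp, mean)
  gy <- tapply(log10(ed), grp, mean)
  keep <- !is.na(gx)
  curve <- data.frame(log10_dist = as.numeric(gx[keep]),
                      dist = 10^as.numeric(gx[keep]),
                      contact = 10^as.numeric(gy[keep]))
  curve <- curve[order(curve$dist), ]
  rownames(curve) <- NULL
  seg <- segments
  seg$exponent <- NA_real_; seg$intercept <- NA_real_
  seg$n_points <- 0L; seg$ok <- FALSE
  for (k in seq_len(nrow(seg))) {
    inseg <- curve$dist > seg$lo[k] & curve$dist <= seg$hi[k]
    seg$n_points[k] <- sum(inseg)
    if (sum(inseg) >= 3) {
      fit <- stats::lm.fit(cbind(1, curve$log10_dist[inseg]),
                           log10(curve$contact[inseg]))
      seg$intercept[k] <- fit$coefficients[1]
      seg$exponent[k] <- fit$coefficients[2]
      seg$ok[k] <- TRUE
    }
  }
  structure(list(curve = curve, segments = seg, resolution = res),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat("decay_curve:", nrow(x$curve), "distance bins\n")
  print(x$segments[c("name", "exponent", "n_points", "ok")])
  invisible(x)
}

#' Cumulative cis interactions by genomic distance
#'
#' @param m A [contact_matrix()].
#' @return Data frame with `dist` (bp), `cumulative` contact total up to and
#'   including that distance, and `fraction` (normalized variant, ends at 1).
#' @export
cumulative_cis_by_distance <- function(m) {
  genome <- attr(m$bins, "genome")
  res <- attr(m$bins, "resolution")
  nmax <- max(chrom_nbins(m$bins))
  sums <- numeric(nmax)
  for (ch in names(genome)) {
    st <- distance_sums(m, ch)
    k <- length(st$sums)
    sums[1:k] <- sums[1:k] + st$sums
  }
  cum <- cumsum(sums)
  tot <- cum[length(cum)]
  data.frame(dist = (seq_along(sums) - 1) * res, cumulative = cum,
             fraction = if (tot > 0) cum / tot else NA_real_)
}

#' Collapsed inter-chromosome interaction clustering
#'
#' Collapses the trans part of a genome-wide matrix to a chromosome-by-
#' chromosome matrix of mean normalized trans signal per pair (a mean, not a
#' sum, so chromosome length does not dominate), computes the Pearson
#' correlation between chromosome rows and clusters chromosomes by
#' average-linkage hierarchical clustering on 1 - correlation.
#'
#' @param m A genome-wide normalized [contact_matrix()] with at least 3
#'   chromosomes.
#' @return List with `collapsed`, `correlation`, `hclust` and `order`
#'   (chromosome names in dendrogram order).
#' @export
chromosome_cluster <- function(m) {
  genome <- attr(m$bins, "genome")
  chroms <- names(genome)
  if (length(chroms) < 3) stop("chromosome clustering needs >= 3 chromosomes")
  k <- length(chroms)
  collapsed <- matrix(NA_real_, k, k, dimnames = list(chroms, chroms))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    blk <- cm_block(m, chroms[a], chroms[b])
    ka <- !cm_block_mask(m, chroms[a]); kb <- !cm_block_mask(m, chroms[b])
    v <- mean(blk[ka, kb, drop = FALSE])
    collapsed[a, b] <- collapsed[b, a] <- v
  }
  corr <- stats::cor(t(collapsed), use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  list(collapsed = collapsed, correlation = corr, hclust = hc,
       order = chroms[hc$order])
}
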