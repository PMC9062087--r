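#' Insulation score along the matrix diagonal
#'
#' For each bin `i`, the raw score is the mean contact in the `w x w` square
#' upstream-by-downstream of the bin — rows `i-w..i-1` by columns
#' `i+1..i+w` — over unmasked pairs: the amount of signal crossing the bin.
#' The normalized score is `log2(raw / chromosome mean of raw)`, defined
#' only where the raw score is positive and the square fits inside the
#' chromosome. A lower score means stronger insulation; TAD boundaries are
#' valleys of this track.
#'
#' @param m A normalized [contact_matrix()] at TAD resolution.
#' @param w Square size in bins (default 10, i.e. 500 kb at 50 kb bins).
#' @return An `insulation_track`: data.frame with `chrom`, `start`, `end`,
#'   `index`, `raw`, `score` (normalized).
#' @export
insulation_score <- function(m, w = 10) {
  stopifnot(w >= 2)
  bins <- m$bins
  raw <- rep(NA_real_, nrow(bins))
  for (ch in names(attr(bins, "genome"))) {
    r <- chrom_bin_range(bins, ch)
    n <- r[2] - r[1] + 1
    if (n < 2 * w + 1) next                  # too short: all-NA track
    blk <- cm_block(m, ch)
    keep <- !cm_block_mask(m, ch)
    for (i in (w + 1):(n - w)) {
      rows <- (i - w):(i - 1); cols <- (i + 1):(i + w)
      ok <- outer(keep[rows], keep[cols], "&")
      if (!any(ok)) next
      raw[r[1] + i - 1] <- mean(blk[rows, cols][ok])
    }
  }
  score <- rep(NA_real_, length(raw))
  for (ch in names(attr(bins, "genome"))) {
    r <- chrom_bin_range(bins, ch)
    v <- raw[r[1]:r[2]]
    mu <- mean(v[!is.na(v) & v > 0])
    if (is.finite(mu) && mu > 0) {
      ok <- !is.na(v) & v > 0
      score[r[1]:r[2]][ok] <- log2(v[ok] / mu)
    }
  }
  out <- data.frame(bins[c("chrom", "start", "end", "index")],
                    raw = raw, score = score, stringsAsFactors = FALSE)
  structure(out, resolution = attr(bins, "resolution"),
            genome = attr(bins, "genome"), w = w,
            class = c("insulation_track", "data.frame"))
}

#' Call TAD boundaries as insulation-score valleys
#'
#' Uses a delta track `delta(i) = mean(score[i+1..i+d]) - mean(score[i-d..
#' i-1])`: negative while the score falls, positive while it rises, so a
#' valley is a left-to-right crossing from negative to non-negative delta.
#' Boundary strength is the delta rise across the valley — the nearest local
#' maximum of delta after the crossing minus the nearest local minimum
#' before it — and boundaries weaker than `threshold` are dropped.
#'
#' @param track An `insulation_track`.
#' @param d Delta window in bins (default 2).
#' @param threshold Minimum strength (default 0.1).
#' @return A `boundary_set`: data.frame with `chrom`, `bin` (global index),
#'   `start`, `end`, `strength`.
#' @export
call_boundaries <- function(track, d = 2, threshold = 0.1) {
  out <- list()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    s <- track$score[sel]
    n <- length(s)
    delta <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ahead <- (i + 1):(i + d); behind <- (i - d):(i - 1)
      if (i + d > n || i - d < 1) next
      if (anyNA(s[ahead]) || anyNA(s[behind])) next
      delta[i] <- mean(s[ahead]) - mean(s[behind])
    }
    for (i in which(!is.na(delta))) {
      if (i == 1 || is.na(delta[i - 1])) next
      if (!(delta[i - 1] < 0 && delta[i] >= 0)) next
      # nearest local max of delta at/after the crossing
      hi <- i
      while (hi < n && !is.na(delta[hi + 1]) && delta[hi + 1] >= delta[hi])
        hi <- hi + 1
      lo <- i - 1
      while (lo > 1 && !is.na(delta[lo - 1]) && delta[lo - 1] <= delta[lo])
        lo <- lo - 1
      strength <- delta[hi] - delta[lo]
      if (is.na(strength) || strength < threshold) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, bin = track$index[sel[i]],
        start = track$start[sel[i]], end = track$end[sel[i]],
        strength = strength, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), bin = integer(), start = numeric(),
               end = numeric(), strength = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, genome = attr(track, "genome"),
            resolution = attr(track, "resolution"),
            class = c("boundary_set", "data.frame"))
}

#' Derive TADs from a boundary set
#'
#' TADs are the intervals between consecutive boundaries of a chromosome,
#' plus the flanking intervals to the chromosome ends.
#'
#' @param boundaries A `boundary_set`.
#' @return A `tad_set`: data.frame with `chrom`, `start`, `end`, `size_bp`
#'   and the flanking boundary bins (`NA` at chromosome ends).
#' @export
tads_from_boundaries <- function(boundaries) {
  genome <- attr(boundaries, "genome")
  out <- list()
  for (ch in names(genome)) {
    b <- boundaries[boundaries$chrom == ch, , drop = FALSE]
    b <- b[order(b$bin), , drop = FALSE]
    cuts <- c(0, b$start + (b$end - b$start) / 2, unname(genome[[ch]]))
    left_bin <- c(NA, b$bin); right_bin <- c(b$bin, NA)
    keep <- diff(cuts) > 0
    out[[ch]] <- data.frame(
      chrom = ch, start = cuts[-length(cuts)][keep], end = cuts[-1][keep],
      left_bin = left_bin[keep], right_bin = right_bin[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$size_bp <- res$end - res$start
  rownames(res) <- NULL
  structure(res, genome = genome,
            resolution = attr(boundaries, "resolution"),
            class = c("tad_set", "data.frame"))
}

#' Compare boundary sets between two conditions
#'
#' Greedy nearest-first one-to-one matching of boundaries within
#' `tolerance` bins on the same chromosome; unmatched boundaries are
#' condition-specific.
#'
#' @param a,b `boundary_set`s on the same bin table.
#' @param tolerance Matching tolerance in bins (default 1).
#' @return A `boundary_comparison`: list with `pairs` (matched bins),
#'   `specific_a`, `specific_b` (subsets of the inputs), and the inputs.
#' @export
compare_boundaries <- function(a, b, tolerance = 1) {
  if (!isTRUE(all.equal(attr(a, "resolution"), attr(b, "resolution"))))
    stop("boundary sets are at different resolutions")
  matched_a <- logical(nrow(a)); matched_b <- logical(nrow(b))
  pairs <- list()
  cand <- list()
  for (ia in seq_len(nrow(a))) {
    jb <- which(b$chrom == a$chrom[ia] & abs(b$bin - a$bin[ia]) <= tolerance)
    if (length(jb))
      cand[[length(cand) + 1]] <- data.frame(
        ia = ia, jb = jb, dist = abs(b$bin[jb] - a$bin[ia]))
  }
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$dist, cand$ia, cand$jb), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      ia <- cand$ia[k]; jb <- cand$jb[k]
      if (matched_a[ia] || matched_b[jb]) next
      matched_a[ia] <- TRUE; matched_b[jb] <- TRUE
      pairs[[length(pairs) + 1]] <- data.frame(
        chrom = a$chrom[ia], bin_a = a$bin[ia], bin_b = b$bin[jb])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chrom = character(), bin_a = integer(), bin_b = integer())
  structure(list(pairs = pairs,
                 specific_a = a[!matched_a, , drop = FALSE],
                 specific_b = b[!matched_b, , drop = FALSE],
                 a = a, b = b, tolerance = tolerance),
            class = "boundary_comparison")
}

#' @export
print.boundary_comparison <- function(x, ...) {
  cat(sprintf("boundary_comparison: %d shared, %d specific to A, %d specific to B (tolerance %d bin)\n",
              nrow(x$pairs), nrow(x$specific_a), nrow(x$specific_b),
              x$tolerance))
  invisible(x)
}

#' Flag altered TADs and per-chromosome altered fractions
#'
#' A TAD is altered iff it touches any condition-specific boundary (from
#' either condition): a specific flanking boundary, or a specific boundary
#' of the other condition falling inside it, both mark the domain as changed.
#'
#' @param comparison A `boundary_comparison`.
#' @param tads A `tad_set` (typically from one of the compared conditions).
#' @return List with `tads` (input plus logical `altered`) and `fractions`
#'   (per-chromosome altered TAD length / chromosome length).
#' @export
altered_tads <- function(comparison, tads) {
  res <- attr(tads, "resolution")
  spec <- rbind(comparison$specific_a[c("chrom", "start", "end")],
                comparison$specific_b[c("chrom", "start", "end")])
  altered <- rep(FALSE, nrow(tads))
  if (nrow(spec)) {
    for (k in seq_len(nrow(tads))) {
      altered[k] <- any(spec$chrom == tads$chrom[k] &
                          spec$end >= tads$start[k] &
                          spec$start <= tads$end[k])
    }
  }
  tads$altered <- altered
  genome <- attr(tads, "genome")
  fr <- vapply(names(genome), function(ch) {
    sum(tads$size_bp[tads$chrom == ch & tads$altered]) / unname(genome[[ch]])
  }, numeric(1))
  list(tads = tads, fractions = fr)
}

#' Difference of two insulation tracks
#'
#' @param a,b `insulation_track`s on the same bin table.
#' @return Data frame with per-bin `delta_score` = a - b (NA where either
#'   undefined).
#' @export
delta_insulation <- function(a, b) {
  if (!identical(a$index, b$index) || !identical(a$chrom, b$chrom))
    stop("insulation tracks are on different bin tables")
  data.frame(a[c("chrom", "start", "end", "index")],
             delta_score = a$score - b$score, stringsAsFactors = FALSE)
}

#' TAD size statistics: altered vs stable
#'
#' Reports median and mean sizes per group and a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie correction) for a size
#' shift between altered and stable TADs.
#'
#' @param tads A `tad_set` with logical `altered` column (see
#'   [altered_tads()]).
#' @return List with `summary` data.frame and `test` (htest).
#' @export
tad_size_stats <- function(tads) {
  stopifnot("altered" %in% names(tads))
  grp <- ifelse(tads$altered, "altered", "stable")
  sm <- do.call(rbind, lapply(split(tads$size_bp, grp), function(v)
    data.frame(n = length(v), median_bp = stats::median(v),
               mean_bp = mean(v))))
  sm <- data.frame(group = rownames(sm), sm, row.names = NULL)
  test <- NULL
  if (length(unique(grp)) == 2)
    test <- stats::wilcox.test(size_bp ~ altered, data = tads,
                               exact = FALSE, correct = FALSE)
  list(summary = sm, test = test)
}
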