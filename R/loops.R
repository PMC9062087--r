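#' Identify condition-specific loops between two loop sets
#'
#' A loop in one set is shared iff a single loop in the other set matches
#' BOTH of its anchors, each within `tolerance` anchor bins (anchor bin =
#' anchor start / loop-calling resolution); one matching anchor is not
#' enough. Matching is one-to-one, greedy by total anchor distance; loops
#' left unmatched are specific to their set. With the default tolerance of
#' 0 this is exact anchor-bin identity — "unique by both anchors".
#'
#' @param a,b `loop_set`s at a common anchor resolution.
#' @param tolerance Per-anchor tolerance in bins (default 0).
#' @param resolution Anchor resolution in bp; defaults to the modal anchor
#'   width of `a`. Mixed anchor widths without an explicit resolution are an
#'   error.
#' @return A `loop_comparison`: list with `shared` (matched index pairs),
#'   `specific_a`, `specific_b`, per-chromosome counts, and inputs.
#' @export
specific_loops <- function(a, b, tolerance = 0, resolution = NULL) {
  infer_res <- function(l) {
    w <- c(l$end1 - l$start1, l$end2 - l$start2)
    u <- unique(w)
    if (length(u) > 1 && is.null(resolution))
      stop("mixed anchor widths; supply an explicit resolution")
    u[1]
  }
  if (is.null(resolution)) {
    resolution <- if (nrow(a)) infer_res(a) else if (nrow(b)) infer_res(b) else 1
    if (nrow(a) && nrow(b) && !identical(infer_res(a), infer_res(b)))
      stop("loop sets have different anchor widths; supply a resolution")
  }
  abin1 <- floor(a$start1 / resolution); abin2 <- floor(a$start2 / resolution)
  bbin1 <- floor(b$start1 / resolution); bbin2 <- floor(b$start2 / resolution)
  cand <- list()
  for (ia in seq_len(nrow(a))) {
    d1 <- abs(bbin1 - abin1[ia]); d2 <- abs(bbin2 - abin2[ia])
    jb <- which(b$chrom == a$chrom[ia] & d1 <= tolerance & d2 <= tolerance)
    if (length(jb))
      cand[[length(cand) + 1]] <- data.frame(ia = ia, jb = jb,
                                             dist = d1[jb] + d2[jb])
  }
  matched_a <- logical(nrow(a)); matched_b <- logical(nrow(b))
  shared <- list()
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$dist, cand$ia, cand$jb), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      ia <- cand$ia[k]; jb <- cand$jb[k]
      if (matched_a[ia] || matched_b[jb]) next
      matched_a[ia] <- TRUE; matched_b[jb] <- TRUE
      shared[[length(shared) + 1]] <- data.frame(ia = ia, jb = jb)
    }
  }
  shared <- if (length(shared)) do.call(rbind, shared) else
    data.frame(ia = integer(), jb = integer())
  per_chrom <- function(l, spec) {
    tab <- table(l$chrom)
    st <- table(l$chrom[spec])
    data.frame(chrom = names(tab), n = as.integer(tab),
               n_specific = as.integer(st[names(tab)]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  ca <- per_chrom(a, !matched_a); ca$n_specific[is.na(ca$n_specific)] <- 0L
  cb <- per_chrom(b, !matched_b); cb$n_specific[is.na(cb$n_specific)] <- 0L
  structure(list(shared = shared,
                 specific_a = a[!matched_a, , drop = FALSE],
                 specific_b = b[!matched_b, , drop = FALSE],
                 counts_a = ca, counts_b = cb,
                 a = a, b = b, tolerance = tolerance,
                 resolution = resolution),
            class = "loop_comparison")
}

#' @export
print.loop_comparison <- function(x, ...) {
  cat(sprintf("loop_comparison: %d shared, %d specific to A, %d specific to B\n",
              nrow(x$shared), nrow(x$specific_a), nrow(x$specific_b)))
  invisible(x)
}

#' Loop length (anchor midpoint distance)
#'
#' @param loops A `loop_set`.
#' @return Numeric vector of lengths in bp.
#' @export
loop_length <- function(loops) {
  (loops$start2 + loops$end2) / 2 - (loops$start1 + loops$end1) / 2
}

#' Compare loop length distributions between two sets
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) on anchor-midpoint loop lengths.
#'
#' @param a,b Nonempty `loop_set`s.
#' @return List with `summary` data.frame (n, median, mean per set) and
#'   `test` (htest).
#' @export
loop_length_stats <- function(a, b) {
  if (!nrow(a) || !nrow(b)) stop("loop sets must be nonempty")
  la <- loop_length(a); lb <- loop_length(b)
  summary <- data.frame(set = c("a", "b"), n = c(length(la), length(lb)),
                        median_bp = c(stats::median(la), stats::median(lb)),
                        mean_bp = c(mean(la), mean(lb)))
  test <- stats::wilcox.test(la, lb, exact = FALSE, correct = FALSE)
  list(summary = summary, test = test)
}

#' Flag genes overlapping loop anchors
#'
#' A gene is at an anchor iff its interval overlaps any anchor interval by
#' at least 1 bp (0-based half-open).
#'
#' @param loops A `loop_set` (for example the specific loops of one
#'   condition).
#' @param genes A `gene_table`.
#' @return The gene table with an added logical `at_anchor` column.
#' @export
genes_at_anchors <- function(loops, genes) {
  anchors <- GenomicRanges::GRanges(
    seqnames = rep(loops$chrom, 2),
    ranges = IRanges::IRanges(start = c(loops$start1, loops$start2) + 1,
                              end = c(loops$end1, loops$end2)))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end))
  genes$at_anchor <- IRanges::overlapsAny(gr, anchors)
  genes
}
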