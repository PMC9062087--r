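#' Pearson chi-square test on a contingency table
#'
#' No continuity correction. Degenerate tables (a zero row or column
#' margin) return statistic 0 with p 1: observed equals expected wherever
#' the expected count is positive.
#'
#' @param tab Numeric matrix of counts.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
contingency_chisq <- function(tab) {
  tab <- as.matrix(tab)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = 0, df = df, p.value = 1))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Annotate genes with compartment, TAD and loop alteration status
#'
#' Compartment switch class is that of the bin containing the gene midpoint;
#' TAD stability is `"altered"` iff the midpoint lies in an altered TAD;
#' loop-anchor status is `TRUE` iff the gene overlaps any specific-loop
#' anchor by at least 1 bp. An `overlap` assignment mode ("any overlap with
#' a class/TAD counts") is available for the first two axes.
#'
#' @param genes A `gene_table`.
#' @param switch_track A `switch_track` from [classify_switch()], or `NULL`.
#' @param tads A `tad_set` with `altered` column (see [altered_tads()]), or
#'   `NULL`. Pass the union of both conditions' TADs to mark a gene altered
#'   if it is altered in either.
#' @param specific_loop_anchors A `loop_set` of condition-specific loops
#'   (anchors taken from both ends), or `NULL`.
#' @param mode `"midpoint"` (default) or `"overlap"`.
#' @return The gene table with added `switch_class`, `tad_status`,
#'   `at_altered_anchor` columns (NA where the input track is missing or the
#'   gene falls outside it).
#' @export
annotate_genes <- function(genes, switch_track = NULL, tads = NULL,
                           specific_loop_anchors = NULL,
                           mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  mid <- floor((genes$start + genes$end) / 2)
  gr_mid <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(mid + 1, mid + 1))
  gr_full <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1,
                                                     genes$end))
  gq <- if (mode == "midpoint") gr_mid else gr_full
  genes$switch_class <- NA_character_
  if (!is.null(switch_track)) {
    tr <- GenomicRanges::GRanges(switch_track$chrom,
                                 IRanges::IRanges(switch_track$start + 1,
                                                  switch_track$end))
    hit <- GenomicRanges::findOverlaps(gq, tr, select = "first")
    ok <- !is.na(hit)
    genes$switch_class[ok] <- switch_track$class[hit[ok]]
  }
  genes$tad_status <- NA_character_
  if (!is.null(tads)) {
    td <- GenomicRanges::GRanges(tads$chrom,
                                 IRanges::IRanges(floor(tads$start) + 1,
                                                  ceiling(tads$end)))
    hit <- GenomicRanges::findOverlaps(gq, td, select = "first")
    ok <- !is.na(hit)
    genes$tad_status[ok] <- ifelse(tads$altered[hit[ok]], "altered", "stable")
  }
  genes$at_altered_anchor <- NA
  if (!is.null(specific_loop_anchors)) {
    if (nrow(specific_loop_anchors)) {
      anch <- GenomicRanges::GRanges(
        rep(specific_loop_anchors$chrom, 2),
        IRanges::IRanges(c(specific_loop_anchors$start1,
                           specific_loop_anchors$start2) + 1,
                         c(specific_loop_anchors$end1,
                           specific_loop_anchors$end2)))
      genes$at_altered_anchor <- IRanges::overlapsAny(gr_full, anch)
    } else {
      genes$at_altered_anchor <- FALSE
    }
  }
  genes
}

#' Up/down-regulation contingency by compartment switch class
#'
#' Groups genes into stable (A2A or B2B), A2B and B2A compartment classes
#' and reports the up/down-regulated count and ratio per group, plus a
#' Pearson chi-square test of each switched class against the stable group.
#'
#' @param annotations Gene table from [annotate_genes()] with `status` and
#'   `switch_class` columns.
#' @return An `updown_result`: list with `counts` data.frame (group, up,
#'   down, ratio, flag) and `tests` data.frame (group, chisq, df, p,
#'   direction).
#' @export
updown_by_class <- function(annotations) {
  grp <- rep(NA_character_, nrow(annotations))
  grp[annotations$switch_class %in% c("A2A", "B2B")] <- "stable"
  grp[annotations$switch_class %in% "A2B"] <- "A2B"
  grp[annotations$switch_class %in% "B2A"] <- "B2A"
  up <- vapply(c("stable", "A2B", "B2A"), function(g)
    sum(grp == g & annotations$status == "up", na.rm = TRUE), numeric(1))
  down <- vapply(c("stable", "A2B", "B2A"), function(g)
    sum(grp == g & annotations$status == "down", na.rm = TRUE), numeric(1))
  updown_from_counts(up, down)
}

#' @rdname updown_by_class
#' @param up,down Named numeric vectors of up- and down-regulated gene
#'   counts for groups `stable`, `A2B`, `B2A` (in that order if unnamed).
#' @export
updown_from_counts <- function(up, down) {
  groups <- c("stable", "A2B", "B2A")
  if (!is.null(names(up))) up <- up[groups]
  if (!is.null(names(down))) down <- down[groups]
  ratio <- ifelse(down > 0, up / down, ifelse(up > 0, Inf, NA_real_))
  flag <- ifelse(down > 0, "ok", ifelse(up > 0, "infinite", "undefined"))
  counts <- data.frame(group = groups, up = as.numeric(up),
                       down = as.numeric(down), ratio = ratio, flag = flag,
                       stringsAsFactors = FALSE)
  tests <- lapply(c("A2B", "B2A"), function(g) {
    i <- match(g, groups)
    tab <- rbind(c(up[i], down[i]), c(up[1], down[1]))
    ct <- contingency_chisq(tab)
    direction <- if (!is.na(ratio[i]) && !is.na(ratio[1])) {
      if (ratio[i] > ratio[1]) "up-enriched" else
        if (ratio[i] < ratio[1]) "down-enriched" else "none"
    } else NA_character_
    data.frame(group = g, chisq = ct$statistic, df = ct$df, p = ct$p.value,
               direction = direction, stringsAsFactors = FALSE)
  })
  structure(list(counts = counts, tests = do.call(rbind, tests)),
            class = "updown_result")
}

#' @export
print.updown_result <- function(x, ...) {
  print(x$counts); print(x$tests)
  invisible(x)
}

#' DEG/NDEG contingency by alteration axis
#'
#' Builds the 2x2 table of differentially vs non-differentially expressed
#' genes against altered vs stable status for one axis (compartment switch,
#' TAD alteration, or specific-loop anchors) with the DEG/NDEG ratio per
#' group and a Pearson chi-square test.
#'
#' @param annotations Gene table from [annotate_genes()].
#' @param axis One of `"compartment"`, `"tad"`, `"loop"`.
#' @return List with `table` (2x2), `ratios` (DEG/NDEG per group), `chisq`,
#'   `df`, `p`; or flagged empty strata without a test.
#' @export
deg_by_alteration <- function(annotations, axis = c("compartment", "tad",
                                                    "loop")) {
  axis <- match.arg(axis)
  altered <- switch(axis,
    compartment = annotations$switch_class %in% c("A2B", "B2A"),
    tad = annotations$tad_status == "altered",
    loop = annotations$at_altered_anchor)
  stable <- switch(axis,
    compartment = annotations$switch_class %in% c("A2A", "B2B"),
    tad = annotations$tad_status == "stable",
    loop = !annotations$at_altered_anchor)
  deg <- annotations$status %in% c("up", "down")
  use <- (altered | stable) & !is.na(altered)
  tab <- rbind(altered = c(sum(deg & altered & use, na.rm = TRUE),
                           sum(!deg & altered & use, na.rm = TRUE)),
               stable = c(sum(deg & stable & use, na.rm = TRUE),
                          sum(!deg & stable & use, na.rm = TRUE)))
  colnames(tab) <- c("DEG", "NDEG")
  if (any(rowSums(tab) == 0)) {
    return(list(axis = axis, table = tab, ratios = NULL, chisq = NA_real_,
                df = 1, p = NA_real_, flag = "empty-stratum"))
  }
  ratios <- ifelse(tab[, "NDEG"] > 0, tab[, "DEG"] / tab[, "NDEG"], Inf)
  ct <- contingency_chisq(tab)
  list(axis = axis, table = tab, ratios = ratios, chisq = ct$statistic,
       df = ct$df, p = ct$p.value, flag = "ok")
}
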