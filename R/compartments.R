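#' Call A/B compartments from a normalized matrix
#'
#' Per chromosome: takes the observed/expected cis block over unmasked bins,
#' forms the Pearson correlation matrix of its columns, extracts the leading
#' eigenvector by symmetric eigendecomposition and orients its sign so that
#' its correlation with a reference activity track (gene density or any
#' A-correlated signal) is non-negative. Bins with positive eigenvector
#' value are labeled `A`, negative `B`; masked bins, chromosomes with fewer
#' than `min_bins` unmasked bins, and exact-zero values are `NA`.
#'
#' @param m A normalized [contact_matrix()] at compartment resolution.
#' @param reference Numeric per-bin reference activity track, aligned to
#'   `m$bins` (higher = more active / A-like). Used only to orient sign.
#' @param min_bins Minimum unmasked bins per chromosome (default 10).
#' @return A `compartment_profile`: data.frame with `chrom`, `start`, `end`,
#'   `index`, `pc1`, `label`.
#' @export
call_compartments <- function(m, reference, min_bins = 10) {
  bins <- m$bins
  stopifnot(length(reference) == nrow(bins))
  oe <- observed_over_expected(m)
  pc1 <- rep(NA_real_, nrow(bins))
  for (ch in names(attr(bins, "genome"))) {
    r <- chrom_bin_range(bins, ch)
    keep <- !cm_block_mask(m, ch)
    blk <- cm_block(oe, ch)[keep, keep, drop = FALSE]
    # O/E rows that are constant carry no plaid signal; treat as masked
    sds <- apply(blk, 2, stats::sd)
    ok <- which(keep)[is.finite(sds) & sds > 0]
    if (length(ok) < min_bins) {
      warning("chromosome ", ch, " has fewer than ", min_bins,
              " informative bins; compartments set to NA")
      next
    }
    blk <- cm_block(oe, ch)[ok, ok, drop = FALSE]
    cc <- stats::cor(blk)
    ev <- eigen(cc, symmetric = TRUE)
    v <- ev$vectors[, 1]
    ref <- reference[r[1]:r[2]][ok]
    if (stats::sd(ref) > 0 && stats::sd(v) > 0 &&
        stats::cor(v, ref) < 0) v <- -v
    pc1[r[1]:r[2]][ok] <- v
  }
  label <- rep(NA_character_, nrow(bins))
  label[!is.na(pc1) & pc1 > 0] <- "A"
  label[!is.na(pc1) & pc1 < 0] <- "B"
  pc1[!is.na(pc1) & pc1 == 0] <- NA_real_
  out <- data.frame(bins[c("chrom", "start", "end", "index")],
                    pc1 = pc1, label = label, stringsAsFactors = FALSE)
  structure(out, resolution = attr(bins, "resolution"),
            genome = attr(bins, "genome"),
            class = c("compartment_profile", "data.frame"))
}

#' Classify per-bin compartment switches between two conditions
#'
#' @param normal,tumor `compartment_profile`s on the same bin table.
#' @return A `switch_track`: data.frame with per-bin `class` in
#'   `{A2A, B2B, A2B, B2A, NA}`, plus attributes `lengths` (bp per class,
#'   genome-wide) and `fractions` (of classified length).
#' @export
classify_switch <- function(normal, tumor) {
  if (!identical(normal$index, tumor$index) ||
      !identical(normal$chrom, tumor$chrom) ||
      !identical(normal$start, tumor$start))
    stop("compartment profiles are on different bin tables")
  cls <- rep(NA_character_, nrow(normal))
  ok <- !is.na(normal$label) & !is.na(tumor$label)
  cls[ok] <- paste0(normal$label[ok], "2", tumor$label[ok])
  width <- normal$end - normal$start
  classes <- c("A2A", "B2B", "A2B", "B2A")
  lens <- vapply(classes, function(k) sum(width[which(cls == k)]), numeric(1))
  fr <- if (sum(lens) > 0) lens / sum(lens) else rep(NA_real_, 4)
  out <- data.frame(normal[c("chrom", "start", "end", "index")],
                    normal = normal$label, tumor = tumor$label,
                    class = cls, stringsAsFactors = FALSE)
  structure(out, lengths = lens, fractions = stats::setNames(fr, classes),
            genome = attr(normal, "genome"),
            class = c("switch_track", "data.frame"))
}

#' Compartment activation ratio
#'
#' Ratio of "activated" (B2A) to "deactivated" (A2B) switched length, per
#' chromosome and genome-wide. When only B2A length is positive the ratio is
#' flagged `infinite`; when both are zero it is flagged `undefined`.
#'
#' @param track A `switch_track` from [classify_switch()].
#' @return Data frame with `chrom` (including `"genome"`), `b2a_bp`,
#'   `a2b_bp`, `ratio` and `flag`.
#' @export
activation_ratio <- function(track) {
  width <- track$end - track$start
  one <- function(sel, name) {
    b2a <- sum(width[sel & track$class == "B2A"], na.rm = TRUE)
    a2b <- sum(width[sel & track$class == "A2B"], na.rm = TRUE)
    if (a2b > 0) {
      data.frame(chrom = name, b2a_bp = b2a, a2b_bp = a2b,
                 ratio = b2a / a2b, flag = "ok", stringsAsFactors = FALSE)
    } else if (b2a > 0) {
      data.frame(chrom = name, b2a_bp = b2a, a2b_bp = a2b, ratio = Inf,
                 flag = "infinite", stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = name, b2a_bp = b2a, a2b_bp = a2b, ratio = NA_real_,
                 flag = "undefined", stringsAsFactors = FALSE)
    }
  }
  sel_all <- !is.na(track$class)
  per <- lapply(unique(track$chrom), function(ch)
    one(sel_all & track$chrom == ch, ch))
  rbind(do.call(rbind, per), one(sel_all, "genome"))
}
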