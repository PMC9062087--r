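#' Configuration for the paired synthetic Hi-C generator
#'
#' Defines every structural ingredient of a paired "normal"/"tumor" dataset:
#' power-law distance decay, compartment plaid, TAD blocks, loop dots,
#' per-bin bias, sequencing depth, trans background and planted
#' translocations. Expected cis contact between bins i and j is
#' `A * (d_ij * resolution)^alpha * plaid(i,j) * tad(i,j) * loop(i,j) *
#' b_i * b_j` (plaid = `plaid_k` when compartment labels agree, TAD =
#' `tad_enrichment` within a domain, loop dots are 3x3 Gaussian bumps);
#' trans contact is a flat background times the biases, with translocated
#' blocks boosted `fold`-times; observed counts are Poisson at the
#' configured depth. The diagonal uses the d = 1 expected value.
#'
#' @param genome A [genome_spec()]; desk-scale by default (3 chromosomes,
#'   90 Mb).
#' @param resolutions Named bp vector with entries `compartment`, `tad`,
#'   `trans`: the matrices emitted per condition.
#' @param alpha Distance-decay exponent (< 0).
#' @param plaid_k Same-compartment multiplicative boost (> 0).
#' @param comp_block_mean_bins Mean compartment block length in compartment
#'   bins.
#' @param b2a_fraction,a2b_fraction Genome fractions switched B-to-A and
#'   A-to-B in the tumor.
#' @param tad_gap_bins Integer range of boundary spacing in TAD bins.
#' @param tad_enrichment Within-TAD contact boost (>= 1).
#' @param boundary_altered_fraction Fraction of boundaries altered
#'   (half deleted, half shifted) in the tumor.
#' @param n_loops_per_chrom,loop_specific_fraction Loop counts and the
#'   fraction specific to each condition.
#' @param loop_fold,loop_sigma_bins Loop dot intensity and width.
#' @param loop_res Anchor resolution of emitted loop lists (bp).
#' @param loop_len_range Loop length range in bp (log-uniform).
#' @param bias_range Per-bin bias range (log-uniform).
#' @param depth Target total counts per emitted matrix.
#' @param trans_rel Trans background as a fraction of the mean cis level.
#' @param translocations Data frame (or `NULL` for none) with columns
#'   `chrom_a`, `start_a`, `chrom_b`, `start_b`, `span_a_bins`,
#'   `span_b_bins` (bins at the trans resolution) and `fold`; planted in
#'   the tumor only. When left unspecified, one 8-fold event (up to 30 x 20
#'   bins, clipped to fit) is planted between the first two chromosomes.
#' @param seed Integer seed driving every random draw.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    genome = genome_spec(c("chr1", "chr2", "chr3"), c(4e7, 3e7, 2e7)),
    resolutions = c(compartment = 5e5, tad = 5e4, trans = 4e4),
    alpha = -1.2,
    plaid_k = 1.5,
    comp_block_mean_bins = 8,
    b2a_fraction = 0.166,
    a2b_fraction = 0.084,
    tad_gap_bins = c(8L, 16L),
    tad_enrichment = 3,
    boundary_altered_fraction = 0.1,
    n_loops_per_chrom = 40,
    loop_specific_fraction = 0.25,
    loop_fold = 4,
    loop_sigma_bins = 1,
    loop_res = 1e4,
    loop_len_range = c(2e5, 2e6),
    bias_range = c(0.5, 2),
    depth = 3e6,
    trans_rel = 0.05,
    translocations = NULL,
    seed = 1L) {
  stopifnot(alpha < 0, plaid_k > 0, tad_enrichment >= 1, depth > 0,
            all(resolutions > 0))
  if (missing(translocations) && length(genome) >= 2) {
    # default event: one 8-fold block a quarter of the way into the first
    # two chromosomes, spans clipped to fit the genome at this resolution
    res <- resolutions[["trans"]]
    la <- unname(genome[[1]]); lb <- unname(genome[[2]])
    sa <- floor(0.25 * la / res) * res
    sb <- floor(lb / 6 / res) * res
    spa <- min(30L, floor((la - sa) / res))
    spb <- min(20L, floor((lb - sb) / res))
    if (spa >= 5 && spb >= 5)
      translocations <- data.frame(chrom_a = names(genome)[1], start_a = sa,
                                   chrom_b = names(genome)[2], start_b = sb,
                                   span_a_bins = as.integer(spa),
                                   span_b_bins = as.integer(spb), fold = 8)
  }
  cfg <- as.list(environment())
  cfg$res <- cfg$la <- cfg$lb <- cfg$sa <- cfg$sb <- cfg$spa <- cfg$spb <- NULL
  if (!is.null(cfg$translocations) && nrow(cfg$translocations)) {
    tr <- cfg$translocations
    res <- resolutions[["trans"]]
    endsA <- tr$start_a + tr$span_a_bins * res
    endsB <- tr$start_b + tr$span_b_bins * res
    if (any(endsA > unname(genome[tr$chrom_a])) ||
        any(endsB > unname(genome[tr$chrom_b])))
      stop("planted translocation span exceeds chromosome length")
  }
  structure(cfg, class = "synthetic_config")
}

# piecewise-constant per-bin value from bp intervals (one chromosome)
intervals_to_bins <- function(starts, values, bin_mids) {
  values[findInterval(bin_mids, starts)]
}

# compartment block layout for one chromosome: data.frame(start, end, label)
gen_comp_blocks <- function(len, res, mean_bins) {
  nb <- ceiling(len / res)
  lens <- integer(); tot <- 0
  while (tot < nb) {
    l <- 2L + stats::rgeom(1, 1 / max(mean_bins - 2, 1))
    lens <- c(lens, min(l, nb - tot)); tot <- tot + l
  }
  lab <- rep(c("A", "B"), length.out = length(lens))
  if (stats::runif(1) < 0.5) lab <- rev(lab)[seq_along(lens)]
  ends <- pmin(cumsum(lens) * res, len)
  data.frame(start = c(0, utils::head(ends, -1)), end = ends, label = lab,
             stringsAsFactors = FALSE)
}

# flip whole blocks toward the target switched genome fraction; a block is
# flipped only if it moves the switched length closer to the target, so the
# realized fraction tracks the target up to half the largest block
flip_blocks <- function(blocks, from, to, target_fraction, genome_len) {
  cand <- which(blocks$label == from & !blocks$switched)
  cand <- cand[sample.int(length(cand))]
  target <- target_fraction * genome_len
  flipped <- 0
  for (k in cand) {
    len <- blocks$end[k] - blocks$start[k]
    if (flipped + len > 1.3 * target) next
    blocks$label[k] <- to
    blocks$switched[k] <- TRUE
    flipped <- flipped + len
  }
  if (flipped == 0 && target > 0 && length(cand)) {
    # every block overshoots: flip the smallest so the class is represented
    lens <- blocks$end[cand] - blocks$start[cand]
    k <- cand[which.min(lens)]
    blocks$label[k] <- to
    blocks$switched[k] <- TRUE
  }
  blocks
}

#' Generate a paired normal/tumor synthetic dataset
#'
#' Draws the planted structure (compartment blocks, TAD boundaries, loops),
#' applies the configured tumor alterations (switched blocks, deleted or
#' shifted boundaries, condition-specific loops, translocations), and
#' samples Poisson contact matrices per condition at each configured
#' resolution. The same seed gives byte-identical output; normal and tumor
#' differ only by the configured alterations (and independent per-condition
#' bias and counting noise).
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_pair`: list with `normal` and `tumor` (each a named
#'   list of `contact_matrix` objects: `compartment`, `tad`, `trans`),
#'   `truth` (planted ground truth) and `config`.
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genome <- config$genome
  res_comp <- config$resolutions[["compartment"]]
  res_tad <- config$resolutions[["tad"]]

  # --- compartment layout, normal then tumor flips -------------------------
  comp_normal <- lapply(names(genome), function(ch)
    gen_comp_blocks(unname(genome[[ch]]), res_comp, config$comp_block_mean_bins))
  names(comp_normal) <- names(genome)
  total_len <- sum(genome)
  comp_tumor <- comp_normal
  for (ch in names(genome)) comp_tumor[[ch]]$switched <- FALSE
  # flip across the whole genome: concatenate, flip, re-split
  all_blocks <- do.call(rbind, lapply(names(genome), function(ch)
    cbind(comp_tumor[[ch]], chrom = ch)))
  all_blocks <- flip_blocks(all_blocks, "B", "A", config$b2a_fraction, total_len)
  all_blocks <- flip_blocks(all_blocks, "A", "B", config$a2b_fraction, total_len)
  comp_tumor <- split(all_blocks, all_blocks$chrom)[names(genome)]

  # --- TAD boundaries ------------------------------------------------------
  bnd_normal <- lapply(names(genome), function(ch) {
    nb <- floor(unname(genome[[ch]]) / res_tad)
    gaps <- integer(); pos <- 0; out <- integer()
    repeat {
      g <- sample(seq(config$tad_gap_bins[1], config$tad_gap_bins[2]), 1)
      pos <- pos + g
      if (pos >= nb - 2) break
      out <- c(out, pos)
    }
    out * res_tad
  })
  names(bnd_normal) <- names(genome)
  bnd_tumor <- bnd_normal
  altered_bp <- stats::setNames(vector("list", length(genome)), names(genome))
  for (ch in names(genome)) {
    b <- bnd_tumor[[ch]]
    n_alt <- round(config$boundary_altered_fraction * length(b))
    if (n_alt == 0) { altered_bp[[ch]] <- numeric(); next }
    pick <- sort(sample(seq_along(b), n_alt))
    del <- pick[seq_len(ceiling(n_alt / 2))]
    shf <- setdiff(pick, del)
    moved <- numeric()
    for (k in shf) {
      shift <- sample(c(-1, 1), 1) * sample(3:5, 1) * res_tad
      moved <- c(moved, b[k] + shift)
      b[k] <- b[k] + shift
    }
    altered_bp[[ch]] <- c(bnd_normal[[ch]][pick], moved)
    b <- sort(b[-del])
    if (any(diff(b) < 2 * res_tad))
      stop("planted TAD boundaries closer than 2 bins after alteration")
    bnd_tumor[[ch]] <- b
  }

  # truth altered-TAD intervals: normal TADs touching any altered boundary
  altered_tad_iv <- do.call(rbind, lapply(names(genome), function(ch) {
    cuts <- c(0, bnd_normal[[ch]], unname(genome[[ch]]))
    iv <- data.frame(chrom = ch, start = utils::head(cuts, -1),
                     end = cuts[-1], stringsAsFactors = FALSE)
    ab <- altered_bp[[ch]]
    iv$altered <- vapply(seq_len(nrow(iv)), function(k)
      any(ab >= iv$start[k] & ab <= iv$end[k]), logical(1))
    iv
  }))

  # --- loops ---------------------------------------------------------------
  lr <- config$loop_res
  draw_loops <- function(ch, n) {
    if (n == 0)
      return(data.frame(chrom = character(), start1 = numeric(),
                        end1 = numeric(), start2 = numeric(),
                        end2 = numeric(), stringsAsFactors = FALSE))
    len <- unname(genome[[ch]])
    ll <- exp(stats::runif(n, log(config$loop_len_range[1]),
                           log(config$loop_len_range[2])))
    ll <- pmax(round(ll / lr) * lr, 2 * lr)
    a1 <- floor(stats::runif(n, 0, len - ll - lr) / lr) * lr
    data.frame(chrom = ch, start1 = a1, end1 = a1 + lr,
               start2 = a1 + ll, end2 = a1 + ll + lr,
               stringsAsFactors = FALSE)
  }
  n_spec <- round(config$loop_specific_fraction * config$n_loops_per_chrom)
  n_shared <- config$n_loops_per_chrom - n_spec
  loops_normal <- list(); loops_tumor <- list()
  for (ch in names(genome)) {
    pool <- draw_loops(ch, n_shared + 2 * n_spec)
    pool <- pool[!duplicated(pool[c("start1", "start2")]), , drop = FALSE]
    while (nrow(pool) < n_shared + 2 * n_spec) {
      pool <- rbind(pool, draw_loops(ch, 2 * n_spec))
      pool <- pool[!duplicated(pool[c("start1", "start2")]), , drop = FALSE]
    }
    pool <- pool[seq_len(n_shared + 2 * n_spec), , drop = FALSE]
    shared <- pool[seq_len(n_shared), , drop = FALSE]
    spec_n <- pool[n_shared + seq_len(n_spec), , drop = FALSE]
    spec_t <- pool[n_shared + n_spec + seq_len(n_spec), , drop = FALSE]
    loops_normal[[ch]] <- rbind(shared, spec_n)
    loops_tumor[[ch]] <- rbind(shared, spec_t)
  }
  as_loopset <- function(lst) {
    df <- do.call(rbind, lst)
    loop_set(df$chrom, df$start1, df$end1, df$chrom, df$start2, df$end2,
             genome = genome)
  }
  loops_normal <- as_loopset(loops_normal)
  loops_tumor <- as_loopset(loops_tumor)

  # --- per-bin labels at arbitrary resolution ------------------------------
  label_track <- function(bins, blocks) {
    out <- character(nrow(bins))
    for (ch in names(genome)) {
      sel <- bins$chrom == ch
      mids <- (bins$start[sel] + bins$end[sel]) / 2
      bl <- blocks[[ch]]
      out[sel] <- intervals_to_bins(bl$start, bl$label, mids)
    }
    out
  }
  tad_track <- function(bins, bnds) {
    out <- integer(nrow(bins))
    for (ch in names(genome)) {
      sel <- bins$chrom == ch
      mids <- (bins$start[sel] + bins$end[sel]) / 2
      out[sel] <- findInterval(mids, bnds[[ch]])
    }
    paste(bins$chrom, out)
  }

  # --- expected matrix and Poisson sampling --------------------------------
  gen_matrix <- function(res, condition) {
    bins <- bin_genome(genome, res)
    nb <- nrow(bins)
    bias <- exp(stats::runif(nb, log(config$bias_range[1]),
                             log(config$bias_range[2])))
    blocks <- if (condition == "normal") comp_normal else comp_tumor
    bnds <- if (condition == "normal") bnd_normal else bnd_tumor
    loops <- if (condition == "normal") loops_normal else loops_tumor
    labs <- label_track(bins, blocks)
    tids <- tad_track(bins, bnds)
    mu_blocks <- list()
    cis_sum <- 0; cis_n <- 0
    for (ch in names(genome)) {
      r <- chrom_bin_range(bins, ch)
      loc <- r[1]:r[2]; n <- length(loc)
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      mu <- (pmax(d, 1) * res)^config$alpha
      same_lab <- outer(labs[loc], labs[loc], "==")
      mu <- mu * ifelse(same_lab, config$plaid_k, 1)
      same_tad <- outer(tids[loc], tids[loc], "==")
      mu <- mu * ifelse(same_tad, config$tad_enrichment, 1)
      lp <- loops[loops$chrom == ch, , drop = FALSE]
      # the dot fold applies at the loop-calling scale; on coarser matrices
      # the focal enrichment is diluted by the bin-size ratio, so a dot
      # stays visible at TAD resolution without dominating compartment maps
      eff_fold <- 1 + (config$loop_fold - 1) * min(1, config$loop_res / res)
      if (nrow(lp) && eff_fold > 1) {
        s2 <- 2 * config$loop_sigma_bins^2
        b1 <- floor(((lp$start1 + lp$end1) / 2) / res) + 1
        b2 <- floor(((lp$start2 + lp$end2) / 2) / res) + 1
        for (k in seq_len(nrow(lp))) for (da in -1:1) for (db in -1:1) {
          ia <- b1[k] + da; ib <- b2[k] + db
          if (ia < 1 || ib < 1 || ia > n || ib > n) next
          f <- 1 + (eff_fold - 1) * exp(-(da^2 + db^2) / s2)
          mu[ia, ib] <- mu[ia, ib] * f
          if (ia != ib) mu[ib, ia] <- mu[ib, ia] * f
        }
      }
      cis_sum <- cis_sum + sum(mu); cis_n <- cis_n + length(mu)
      mu <- mu * outer(bias[loc], bias[loc])
      mu_blocks[[paste(ch, ch)]] <- mu
    }
    trans_base <- config$trans_rel * (cis_sum / cis_n)
    chroms <- names(genome)
    for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
      if (b <= a) next
      ra <- chrom_bin_range(bins, chroms[a]); rb <- chrom_bin_range(bins, chroms[b])
      la <- ra[1]:ra[2]; lb <- rb[1]:rb[2]
      mu <- matrix(trans_base, length(la), length(lb))
      if (condition == "tumor" && !is.null(config$translocations) &&
          nrow(config$translocations)) {
        tr <- config$translocations
        res_tr <- config$resolutions[["trans"]]
        for (k in seq_len(nrow(tr))) {
          pair_fwd <- tr$chrom_a[k] == chroms[a] && tr$chrom_b[k] == chroms[b]
          pair_rev <- tr$chrom_a[k] == chroms[b] && tr$chrom_b[k] == chroms[a]
          if (!pair_fwd && !pair_rev) next
          ea <- tr$start_a[k] + tr$span_a_bins[k] * res_tr
          eb <- tr$start_b[k] + tr$span_b_bins[k] * res_tr
          if (pair_fwd) {
            sel_r <- bins$start[la] >= tr$start_a[k] & bins$end[la] <= ea
            sel_c <- bins$start[lb] >= tr$start_b[k] & bins$end[lb] <= eb
          } else {
            sel_r <- bins$start[la] >= tr$start_b[k] & bins$end[la] <= eb
            sel_c <- bins$start[lb] >= tr$start_a[k] & bins$end[lb] <= ea
          }
          mu[sel_r, sel_c] <- mu[sel_r, sel_c] * tr$fold[k]
        }
      }
      mu <- mu * outer(bias[la], bias[lb])
      mu_blocks[[paste(chroms[a], chroms[b])]] <- mu
    }
    # scale to depth over the upper triangle and sample
    tot <- 0
    for (nm in names(mu_blocks)) {
      parts <- strsplit(nm, " ")[[1]]
      m <- mu_blocks[[nm]]
      tot <- tot + if (parts[1] == parts[2])
        sum(m[upper.tri(m, diag = TRUE)]) else sum(m)
    }
    sc <- config$depth / tot
    trip_i <- integer(); trip_j <- integer(); trip_x <- numeric()
    offs <- chrom_offsets(bins)
    for (nm in names(mu_blocks)) {
      parts <- strsplit(nm, " ")[[1]]
      m <- mu_blocks[[nm]] * sc
      if (parts[1] == parts[2]) {
        idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
      } else {
        idx <- which(matrix(TRUE, nrow(m), ncol(m)), arr.ind = TRUE)
      }
      cnt <- stats::rpois(nrow(idx), m[idx])
      nz <- cnt > 0
      trip_i <- c(trip_i, offs[parts[1]] + idx[nz, 1] - 1L)
      trip_j <- c(trip_j, offs[parts[2]] + idx[nz, 2] - 1L)
      trip_x <- c(trip_x, cnt[nz])
    }
    list(matrix = contact_matrix(bins, trip_i, trip_j, trip_x, kind = "raw"),
         bias = bias)
  }

  matrices <- list(normal = list(), tumor = list())
  biases <- list(normal = list(), tumor = list())
  for (cond in c("normal", "tumor")) {
    for (nm in names(config$resolutions)) {
      g <- gen_matrix(config$resolutions[[nm]], cond)
      matrices[[cond]][[nm]] <- g$matrix
      biases[[cond]][[nm]] <- g$bias
    }
  }

  # --- truth ---------------------------------------------------------------
  comp_bins <- bin_genome(genome, res_comp)
  lab_n <- label_track(comp_bins, comp_normal)
  lab_t <- label_track(comp_bins, comp_tumor)
  truth <- list(
    genome = list(chroms = names(genome), lengths = as.numeric(genome)),
    resolutions = as.list(config$resolutions),
    compartment = data.frame(comp_bins[c("chrom", "start", "end", "index")],
                             normal = lab_n, tumor = lab_t,
                             class = paste0(lab_n, "2", lab_t),
                             stringsAsFactors = FALSE),
    boundaries_normal = bnd_normal,
    boundaries_tumor = bnd_tumor,
    altered_boundaries = altered_bp,
    tads_normal = altered_tad_iv,
    loops_normal = as.data.frame(loops_normal),
    loops_tumor = as.data.frame(loops_tumor),
    translocations = config$translocations,
    breakpoints = if (!is.null(config$translocations) &&
                      nrow(config$translocations)) {
      tr <- config$translocations
      data.frame(chromA = tr$chrom_a, posA = tr$start_a,
                 chromB = tr$chrom_b, posB = tr$start_b,
                 stringsAsFactors = FALSE)
    } else NULL,
    bias = biases,
    seed = config$seed)
  structure(list(normal = matrices$normal, tumor = matrices$tumor,
                 truth = truth, config = config),
            class = "synthetic_pair")
}

#' Generate a gene/expression table tied to planted alterations
#'
#' Places `n_per_class` genes uniformly within bins of each structural
#' class — B2A-switched, A2B-switched, stable compartments, altered TADs and
#' specific-loop anchors — and draws each gene's log2 fold change from a
#' normal distribution centered on the class effect: positive for B2A,
#' negative for A2B, zero for stable, and a random-sign effect for the
#' altered-TAD and loop-anchor classes (alteration predicts differential
#' expression, not its direction). Adjusted p-values come from a two-sided
#' normal test of the realized log2FC against the null spread, BH-corrected.
#'
#' @param truth The `truth` element of a [generate_pair()] result.
#' @param b2a_shift,a2b_shift,tad_effect,loop_effect Class effect sizes on
#'   the log2FC scale (defaults +1.5, -1.5, 1.5, 1.5).
#' @param sigma Within-class log2FC spread (default 0.5).
#' @param n_per_class Genes per class (default 200).
#' @param gene_length Gene length in bp (default 2e4).
#' @param min_spacing Minimum average spacing in bp used for the class
#'   capacity check (default 1e3); genes may overlap within a class.
#' @param seed Integer seed.
#' @param padj_cut,lfc_cut DE thresholds (defaults 0.05 and 1).
#' @return A `gene_table` with `status` and a `class` column recording the
#'   planted class.
#' @export
generate_expression <- function(truth, b2a_shift = 1.5, a2b_shift = -1.5,
                                tad_effect = 1.5, loop_effect = 1.5,
                                sigma = 0.5, n_per_class = 200,
                                gene_length = 2e4, min_spacing = 1e3,
                                seed = 1L,
                                padj_cut = 0.05, lfc_cut = 1) {
  set.seed(seed)
  comp <- truth$compartment
  genome <- genome_spec(truth$genome$chroms, truth$genome$lengths)
  place_in <- function(iv, n) {
    if (!nrow(iv)) stop("no genome intervals available for a gene class")
    w <- iv$end - iv$start
    if (sum(w) < n * min_spacing)
      stop("requested gene count exceeds genome capacity at the minimum ",
           "spacing for a class")
    pick <- sample(nrow(iv), n, replace = TRUE, prob = w)
    start <- floor(iv$start[pick] +
                     stats::runif(n) * pmax(w[pick] - gene_length, 1))
    cap <- unname(genome[iv$chrom[pick]]) - gene_length
    start <- pmin(start, floor(cap))
    data.frame(chrom = iv$chrom[pick], start = start,
               end = start + gene_length, stringsAsFactors = FALSE)
  }
  spec_loops <- function() {
    ln <- truth$loops_normal; lt <- truth$loops_tumor
    key <- function(l) paste(l$chrom, l$start1, l$start2)
    spec <- rbind(ln[!key(ln) %in% key(lt), ], lt[!key(lt) %in% key(ln), ])
    data.frame(chrom = rep(spec$chrom, 2),
               start = c(spec$start1, spec$start2),
               end = c(spec$end1, spec$end2), stringsAsFactors = FALSE)
  }
  classes <- list(
    B2A = list(iv = comp[comp$class == "B2A", c("chrom", "start", "end")],
               shift = b2a_shift, signed = TRUE),
    A2B = list(iv = comp[comp$class == "A2B", c("chrom", "start", "end")],
               shift = a2b_shift, signed = TRUE),
    stable = list(iv = comp[comp$class %in% c("A2A", "B2B"),
                            c("chrom", "start", "end")],
                  shift = 0, signed = TRUE),
    altered_tad = list(iv = truth$tads_normal[truth$tads_normal$altered,
                                              c("chrom", "start", "end")],
                       shift = tad_effect, signed = FALSE),
    loop_anchor = list(iv = spec_loops(), shift = loop_effect,
                       signed = FALSE))
  out <- list()
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    pos <- place_in(cl$iv, n_per_class)
    shift <- if (cl$signed) cl$shift else
      cl$shift * sample(c(-1, 1), n_per_class, replace = TRUE)
    lfc <- stats::rnorm(n_per_class, shift, sigma)
    out[[nm]] <- data.frame(
      gene_id = sprintf("%s_g%04d", nm, seq_len(n_per_class)),
      pos, strand = "+",
      baseMean = round(exp(stats::rnorm(n_per_class, 5, 1)), 2),
      log2FC = round(lfc, 4), class = nm, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, out)
  p <- 2 * stats::pnorm(-abs(genes$log2FC) / sigma)
  genes$padj <- stats::p.adjust(p, method = "BH")
  genes$status <- de_status(genes$log2FC, genes$padj, padj_cut, lfc_cut)
  genes <- genes[c("gene_id", "chrom", "start", "end", "strand", "baseMean",
                   "log2FC", "padj", "class", "status")]
  rownames(genes) <- NULL
  validate_coords(genes$chrom, genes$end, genome, "gene")
  structure(genes, class = c("gene_table", "data.frame"))
}

#' Write a synthetic pair to disk in the package's exchange formats
#'
#' Emits, per condition and resolution, the triplet matrix + bin file; per
#' condition, the loop BEDPE; plus the gene table, SV table, breakpoint
#' table, truth JSON and a manifest (paths, seed, md5 checksums).
#'
#' @param pair A `synthetic_pair` from [generate_pair()].
#' @param dir Output directory (created if missing).
#' @param genes Optional `gene_table` from [generate_expression()].
#' @return The manifest, invisibly; written as `manifest.json`.
#' @export
emit_files <- function(pair, dir, genes = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list()
  for (cond in c("normal", "tumor")) {
    for (nm in names(pair[[cond]])) {
      mf <- file.path(dir, sprintf("%s_%s.matrix", cond, nm))
      bf <- file.path(dir, sprintf("%s_%s.bed", cond, nm))
      write_matrix(pair[[cond]][[nm]], mf, bf)
      paths[[sprintf("%s_%s_matrix", cond, nm)]] <- mf
      paths[[sprintf("%s_%s_bed", cond, nm)]] <- bf
    }
  }
  ln <- file.path(dir, "normal_loops.bedpe")
  lt <- file.path(dir, "tumor_loops.bedpe")
  write_bedpe_loops(structure(pair$truth$loops_normal,
                              class = c("loop_set", "data.frame")), ln)
  write_bedpe_loops(structure(pair$truth$loops_tumor,
                              class = c("loop_set", "data.frame")), lt)
  paths$normal_loops <- ln; paths$tumor_loops <- lt
  if (!is.null(pair$truth$breakpoints)) {
    bp <- file.path(dir, "breakpoints.tsv")
    write_breakpoints(structure(pair$truth$breakpoints,
                                class = c("breakpoint_set", "data.frame")), bp)
    paths$breakpoints <- bp
    tr <- pair$truth$translocations
    res_tr <- pair$config$resolutions[["trans"]]
    svs <- data.frame(
      chrom = c(tr$chrom_a, tr$chrom_b),
      start = c(tr$start_a, tr$start_b),
      end = c(tr$start_a + tr$span_a_bins * res_tr,
              tr$start_b + tr$span_b_bins * res_tr),
      type = "translocation-interval", stringsAsFactors = FALSE)
    svf <- file.path(dir, "svs.tsv")
    write_sv_table(structure(svs, class = c("sv_set", "data.frame")), svf)
    paths$svs <- svf
  }
  if (!is.null(genes)) {
    gf <- file.path(dir, "genes.tsv")
    utils::write.table(as.data.frame(genes), gf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$genes <- gf
  }
  # orientation reference: mean A-indicator across conditions; correlates
  # positively with the plaid of both conditions as long as the switched
  # fraction stays below half the genome
  comp <- pair$truth$compartment
  ref_n <- ifelse(comp$normal == "A", 1, -1)
  ref_t <- ifelse(comp$tumor == "A", 1, -1)
  rf <- file.path(dir, "reference_track.tsv")
  utils::write.table(
    data.frame(chrom = comp$chrom, start = comp$start, end = comp$end,
               value = (ref_n + ref_t) / 2,
               value_normal = ref_n, value_tumor = ref_t),
    rf, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$reference <- rf
  tf <- file.path(dir, "truth.json")
  jsonlite::write_json(truth_to_json(pair$truth), tf, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$truth <- tf
  files <- unlist(paths)
  manifest <- list(seed = pair$truth$seed, files = as.list(files),
                   md5 = as.list(stats::setNames(
                     unname(tools::md5sum(files)), names(files))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

truth_to_json <- function(truth) {
  truth
}

#' Read a truth JSON back into the in-memory form
#'
#' @param file Path to `truth.json` written by [emit_files()].
#' @return The truth list (data.frame fields restored).
#' @export
read_truth <- function(file) {
  tr <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (nm in c("compartment", "tads_normal", "loops_normal", "loops_tumor",
               "translocations", "breakpoints")) {
    if (!is.null(tr[[nm]])) tr[[nm]] <- as.data.frame(tr[[nm]])
  }
  for (nm in c("boundaries_normal", "boundaries_tumor", "altered_boundaries"))
    tr[[nm]] <- lapply(tr[[nm]], as.numeric)
  tr
}
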