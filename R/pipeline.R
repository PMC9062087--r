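#' Build a full-run configuration
#'
#' Collects input paths per condition plus every stage parameter, with the
#' workflow's standard resolutions (500 kb compartments, 50 kb TADs, 10 kb
#' loop anchors, 40 kb translocations) baked into the expected inputs.
#' `run_config_from_yaml()` reads the same structure from a YAML file.
#'
#' @param normal,tumor Named lists with paths: `compartment_matrix`,
#'   `compartment_bed`, `tad_matrix`, `tad_bed`, `trans_matrix`,
#'   `trans_bed`, and optionally `loops` (BEDPE).
#' @param genes,breakpoints,svs Optional table paths.
#' @param reference Optional path to a per-bin activity track (TSV with
#'   header `chrom`, `start`, `end`, `value` at compartment resolution) used
#'   to orient compartment eigenvector signs; when absent, gene density from
#'   the gene table is used.
#' @param out_dir Output directory.
#' @param params Named list overriding defaults (see
#'   [default_run_params()]).
#' @return A `run_config` list.
#' @export
run_config <- function(normal, tumor, genes = NULL, breakpoints = NULL,
                       svs = NULL, reference = NULL,
                       out_dir = "hicpair_out", params = list()) {
  p <- utils::modifyList(default_run_params(), params)
  structure(list(normal = normal, tumor = tumor, genes = genes,
                 breakpoints = breakpoints, svs = svs,
                 reference = reference, out_dir = out_dir, params = p),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_run_params <- function() {
  list(ice_max_iter = 200, ice_tol = 1e-5, coverage_filter_fraction = 0.02,
       insulation_w = 10, boundary_delta = 2, boundary_threshold = 0.1,
       boundary_tolerance = 1, loop_tolerance = 0,
       trans_fold = 4, trans_min_span = 5, edge_tolerance = 1,
       mask_translocations = TRUE, padj_cut = 0.05, lfc_cut = 1,
       min_compartment_bins = 10, seed = 1L)
}

#' @rdname run_config
#' @param file Path to a YAML configuration.
#' @export
run_config_from_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  run_config(normal = y$normal, tumor = y$tumor, genes = y$genes,
             breakpoints = y$breakpoints, svs = y$svs,
             reference = y$reference,
             out_dir = if (is.null(y$out_dir)) "hicpair_out" else y$out_dir,
             params = if (is.null(y$params)) list() else y$params)
}

load_side <- function(side) {
  out <- list(
    compartment = read_matrix(side$compartment_matrix, side$compartment_bed),
    tad = read_matrix(side$tad_matrix, side$tad_bed),
    trans = read_matrix(side$trans_matrix, side$trans_bed))
  if (!is.null(side$loops)) out$loops <- read_bedpe_loops(side$loops)
  out
}

# per-bin gene density, the default compartment orientation reference
gene_density_track <- function(bins, genes) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end))
  br <- GenomicRanges::GRanges(bins$chrom,
                               IRanges::IRanges(bins$start + 1, bins$end))
  GenomicRanges::countOverlaps(br, gr)
}

#' Run the full comparative pipeline
#'
#' Stage order: load, ICE-normalize every matrix, scan the tumor trans
#' matrix for translocation hotspots and double-confirm them against WGS
#' breakpoints, mask confirmed blocks (on by default), then compartments
#' and switch classes, distance decay, insulation/TAD comparison, loop
#' comparison, SV overlap, expression integration, and a structured report
#' written to `out_dir`. Each stage's tabular outputs are cached under
#' `out_dir`.
#'
#' @param config A `run_config`.
#' @return The report list, invisibly; also written as `report.json`.
#' @export
run_full <- function(config) {
  p <- config$params
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[hicpair] ", sprintf(...))
  stage <- function(name, expr) {
    log_msg("stage %s", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  set.seed(p$seed)
  norm_in <- stage("load", load_side(config$normal))
  tum_in <- stage("load", load_side(config$tumor))
  genes <- if (!is.null(config$genes))
    read_gene_table(config$genes, padj_cut = p$padj_cut, lfc_cut = p$lfc_cut)
  breakpoints <- if (!is.null(config$breakpoints))
    read_breakpoints(config$breakpoints)
  svs <- if (!is.null(config$svs)) read_sv_table(config$svs)

  ice <- stage("ice", list(
    normal = lapply(norm_in[c("compartment", "tad", "trans")], function(m)
      ice_normalize(m, p$ice_max_iter, p$ice_tol, p$coverage_filter_fraction)),
    tumor = lapply(tum_in[c("compartment", "tad", "trans")], function(m)
      ice_normalize(m, p$ice_max_iter, p$ice_tol, p$coverage_filter_fraction))))

  events <- stage("translocations", {
    ev <- trans_hotspot_scan(ice$tumor$trans$matrix, fold = p$trans_fold,
                             min_span = p$trans_min_span)
    if (!is.null(breakpoints))
      ev <- double_confirm(ev, breakpoints, p$edge_tolerance)
    ev
  })
  if (p$mask_translocations && nrow(events)) {
    for (cond in c("tumor")) {
      for (nm in names(ice[[cond]]))
        ice[[cond]][[nm]]$matrix <- mask_events(ice[[cond]][[nm]]$matrix,
                                                events)
    }
  }

  comp <- stage("compartments", {
    bins <- ice$normal$compartment$matrix$bins
    if (!is.null(config$reference)) {
      rt <- utils::read.table(config$reference, header = TRUE, sep = "\t")
      if (nrow(rt) != nrow(bins))
        stop("reference track does not match compartment bins")
      # per-condition orientation columns when available (synthetic truth);
      # a single shared activity track otherwise
      ref_n <- if ("value_normal" %in% names(rt)) rt$value_normal else rt$value
      ref_t <- if ("value_tumor" %in% names(rt)) rt$value_tumor else rt$value
    } else if (!is.null(genes)) {
      ref_n <- ref_t <- gene_density_track(bins, genes)
    } else ref_n <- ref_t <- rep(1, nrow(bins))
    cn <- call_compartments(ice$normal$compartment$matrix, ref_n,
                            p$min_compartment_bins)
    ct <- call_compartments(ice$tumor$compartment$matrix, ref_t,
                            p$min_compartment_bins)
    sw <- classify_switch(cn, ct)
    list(normal = cn, tumor = ct, switch = sw,
         activation = activation_ratio(sw))
  })

  # decay fitted on the TAD-resolution matrix: at compartment resolution the
  # sub-megabase segment holds fewer than 3 distance bins
  ide <- stage("ide", list(
    normal = decay_curve(ice$normal$tad$matrix),
    tumor = decay_curve(ice$tumor$tad$matrix),
    cis_trans = list(
      normal = cis_trans_ratio(norm_in$compartment),
      tumor = cis_trans_ratio(tum_in$compartment))))

  tads <- stage("tads", {
    tn <- insulation_score(ice$normal$tad$matrix, p$insulation_w)
    tt <- insulation_score(ice$tumor$tad$matrix, p$insulation_w)
    bn <- call_boundaries(tn, p$boundary_delta, p$boundary_threshold)
    bt <- call_boundaries(tt, p$boundary_delta, p$boundary_threshold)
    cmp <- compare_boundaries(bn, bt, p$boundary_tolerance)
    at_n <- altered_tads(cmp, tads_from_boundaries(bn))
    at_t <- altered_tads(cmp, tads_from_boundaries(bt))
    list(insulation_normal = tn, insulation_tumor = tt,
         boundaries_normal = bn, boundaries_tumor = bt, comparison = cmp,
         altered_normal = at_n, altered_tumor = at_t,
         delta = delta_insulation(tt, tn),
         sizes = tad_size_stats(rbind(at_n$tads, at_t$tads)))
  })

  loops <- if (!is.null(norm_in$loops) && !is.null(tum_in$loops)) {
    stage("loops", {
      cmp <- specific_loops(norm_in$loops, tum_in$loops, p$loop_tolerance)
      list(comparison = cmp,
           lengths = loop_length_stats(norm_in$loops, tum_in$loops))
    })
  } else NULL

  sv_enrich <- if (!is.null(svs)) stage("sv_overlap", {
    bset <- rbind(tads$boundaries_normal, tads$boundaries_tumor)
    spec_bins <- c(tads$comparison$specific_a$bin, tads$comparison$specific_b$bin)
    b_alt <- bset$bin %in% spec_bins
    out <- list(boundaries = sv_overlap_enrichment(
      bset[c("chrom", "start", "end")], b_alt, svs))
    if (!is.null(loops)) {
      lc <- loops$comparison
      all_loops <- rbind(as.data.frame(lc$a), as.data.frame(lc$b))
      spec <- rbind(as.data.frame(lc$specific_a), as.data.frame(lc$specific_b))
      anchors <- data.frame(
        chrom = rep(all_loops$chrom, 2),
        start = c(all_loops$start1, all_loops$start2),
        end = c(all_loops$end1, all_loops$end2))
      key <- paste(rep(all_loops$chrom, 2), c(all_loops$start1, all_loops$start2))
      spec_key <- c(paste(spec$chrom, spec$start1), paste(spec$chrom, spec$start2))
      out$anchors <- sv_overlap_enrichment(anchors, key %in% spec_key, svs)
    }
    out
  }) else NULL

  integ <- if (!is.null(genes)) stage("integration", {
    all_tads <- rbind(tads$altered_normal$tads, tads$altered_tumor$tads)
    spec_anchors <- if (!is.null(loops))
      rbind(as.data.frame(loops$comparison$specific_a),
            as.data.frame(loops$comparison$specific_b)) else NULL
    ann <- annotate_genes(genes, comp$switch, all_tads, spec_anchors)
    res <- list(annotations = ann, updown = updown_by_class(ann),
                deg_compartment = deg_by_alteration(ann, "compartment"),
                deg_tad = deg_by_alteration(ann, "tad"))
    if (!is.null(spec_anchors)) res$deg_loop <- deg_by_alteration(ann, "loop")
    res
  }) else NULL

  report <- stage("report", build_report(config, comp, ide, tads, loops,
                                         events, sv_enrich, integ))
  write_report(report, tads, comp, config$out_dir)
  invisible(report)
}

build_report <- function(config, comp, ide, tads, loops, events, sv_enrich,
                         integ) {
  seg <- function(dc) stats::setNames(as.list(dc$segments$exponent),
                                      dc$segments$name)
  rep <- list(
    seed = config$params$seed,
    parameters = config$params,
    cis_trans = ide$cis_trans,
    ide = list(normal = seg(ide$normal), tumor = seg(ide$tumor)),
    compartments = list(
      fractions = as.list(attr(comp$switch, "fractions")),
      lengths_bp = as.list(attr(comp$switch, "lengths")),
      activation = comp$activation),
    tads = list(
      n_boundaries_normal = nrow(tads$boundaries_normal),
      n_boundaries_tumor = nrow(tads$boundaries_tumor),
      n_shared = nrow(tads$comparison$pairs),
      n_specific_normal = nrow(tads$comparison$specific_a),
      n_specific_tumor = nrow(tads$comparison$specific_b),
      altered_fraction_normal = as.list(tads$altered_normal$fractions),
      altered_fraction_tumor = as.list(tads$altered_tumor$fractions),
      median_tad_bp = stats::median(tads$altered_normal$tads$size_bp)),
    loops = if (is.null(loops)) list(status = "not run") else list(
      status = "run",
      n_normal = nrow(loops$comparison$a),
      n_tumor = nrow(loops$comparison$b),
      n_shared = nrow(loops$comparison$shared),
      n_specific_normal = nrow(loops$comparison$specific_a),
      n_specific_tumor = nrow(loops$comparison$specific_b),
      median_length_normal = loops$lengths$summary$median_bp[1],
      median_length_tumor = loops$lengths$summary$median_bp[2],
      length_test_p = loops$lengths$test$p.value),
    translocations = as.data.frame(events),
    sv_overlap = if (is.null(sv_enrich)) list(status = "not run") else
      lapply(sv_enrich, as.data.frame),
    integration = if (is.null(integ)) list(status = "not run") else list(
      status = "run",
      updown = integ$updown$counts,
      updown_tests = integ$updown$tests,
      deg_compartment = unclass_contingency(integ$deg_compartment),
      deg_tad = unclass_contingency(integ$deg_tad),
      deg_loop = if (is.null(integ$deg_loop)) NULL else
        unclass_contingency(integ$deg_loop)))
  rep
}

unclass_contingency <- function(x) {
  list(table = as.data.frame(x$table), ratios = as.list(x$ratios),
       chisq = x$chisq, df = x$df, p = x$p, flag = x$flag)
}

write_report <- function(report, tads, comp, out_dir) {
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows", na = "null")
  utils::write.table(as.data.frame(comp$switch),
                     file.path(out_dir, "switch_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comp$activation,
                     file.path(out_dir, "activation_ratio.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(tads$boundaries_normal),
                     file.path(out_dir, "boundaries_normal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(tads$boundaries_tumor),
                     file.path(out_dir, "boundaries_tumor.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
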