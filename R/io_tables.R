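#' Read chromatin loops from a BEDPE file
#'
#' Standard BEDPE columns (chrom1, start1, end1, chrom2, start2, end2,
#' optional score), 0-based half-open. Anchors are canonicalized so anchor 1
#' precedes anchor 2; inter-chromosomal rows are dropped with a warning
#' count, since loop callers in this workflow emit intra-chromosomal loops
#' only.
#'
#' @param file Path to a BEDPE file (no header).
#' @param genome Optional [genome_spec()] for coordinate validation.
#' @return A `loop_set`: data.frame with columns `chrom`, `start1`, `end1`,
#'   `start2`, `end2`, `score`, with attribute `n_dropped_trans`.
#' @export
read_bedpe_loops <- function(file, genome = NULL) {
  df <- utils::read.table(file, header = FALSE, sep = "\t", fill = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BEDPE needs at least 6 columns: ", file)
  score <- if (ncol(df) >= 7) suppressWarnings(as.numeric(df[[7]])) else NA_real_
  loops <- loop_set(chrom1 = df[[1]], start1 = df[[2]], end1 = df[[3]],
                    chrom2 = df[[4]], start2 = df[[5]], end2 = df[[6]],
                    score = score, genome = genome)
  loops
}

#' Construct a canonical intra-chromosomal loop set
#'
#' @param chrom1,start1,end1,chrom2,start2,end2 Anchor coordinates
#'   (0-based half-open).
#' @param score Optional numeric score.
#' @param genome Optional [genome_spec()] for validation.
#' @return A `loop_set` data.frame; inter-chromosomal rows are dropped and
#'   counted in attribute `n_dropped_trans`.
#' @export
loop_set <- function(chrom1, start1, end1, chrom2, start2, end2,
                     score = NA_real_, genome = NULL) {
  n <- length(chrom1)
  score <- rep_len(score, max(n, 1L))
  intra <- chrom1 == chrom2
  n_dropped <- sum(!intra)
  if (n_dropped)
    warning(n_dropped, " inter-chromosomal loop row(s) dropped")
  keep <- which(intra)
  s1 <- as.numeric(start1[keep]); e1 <- as.numeric(end1[keep])
  s2 <- as.numeric(start2[keep]); e2 <- as.numeric(end2[keep])
  swap <- s1 > s2
  tmp_s <- s1[swap]; tmp_e <- e1[swap]
  s1[swap] <- s2[swap]; e1[swap] <- e2[swap]
  s2[swap] <- tmp_s; e2[swap] <- tmp_e
  out <- data.frame(chrom = as.character(chrom1[keep]),
                    start1 = s1, end1 = e1, start2 = s2, end2 = e2,
                    score = score[keep], stringsAsFactors = FALSE)
  if (any(out$start1 >= out$end1) || any(out$start2 >= out$end2))
    stop("loop anchors must have start < end")
  if (!is.null(genome)) {
    if (!all(out$chrom %in% names(genome)))
      stop("loop on unknown chromosome")
    if (any(out$end2 > unname(genome[out$chrom])))
      stop("loop anchor beyond chromosome end")
  }
  rownames(out) <- NULL
  structure(out, n_dropped_trans = n_dropped,
            class = c("loop_set", "data.frame"))
}

#' @rdname read_bedpe_loops
#' @param loops A `loop_set`.
#' @export
write_bedpe_loops <- function(loops, file) {
  sc <- ifelse(is.na(loops$score), ".", format_num(loops$score))
  writeLines(paste(loops$chrom, format_num(loops$start1), format_num(loops$end1),
                   loops$chrom, format_num(loops$start2), format_num(loops$end2),
                   sc, sep = "\t"), file)
  invisible(file)
}

#' Assign differential-expression status from effect size and significance
#'
#' @param log2fc Log2 fold changes.
#' @param padj Adjusted p-values.
#' @param padj_cut Significance cutoff on `padj` (default 0.05).
#' @param lfc_cut Minimum absolute log2 fold change (default 1).
#' @return Character vector in `c("up", "down", "not-DE")`.
#' @export
de_status <- function(log2fc, padj, padj_cut = 0.05, lfc_cut = 1) {
  status <- rep("not-DE", length(log2fc))
  sig <- !is.na(padj) & padj < padj_cut & !is.na(log2fc) & abs(log2fc) >= lfc_cut
  status[sig & log2fc > 0] <- "up"
  status[sig & log2fc < 0] <- "down"
  status
}

#' Read a gene table with differential-expression results
#'
#' Tab-separated with header and columns `gene_id`, `chrom`, `start`, `end`,
#' `strand`, `baseMean`, `log2FC`, `padj`. DE status is derived from the
#' thresholds in effect (defaults: adjusted p < 0.05, |log2FC| >= 1).
#'
#' @param file Path to the TSV.
#' @param genome Optional [genome_spec()] for validation.
#' @param padj_cut,lfc_cut Thresholds passed to [de_status()].
#' @return A `gene_table` data.frame with an added `status` column.
#' @export
read_gene_table <- function(file, genome = NULL, padj_cut = 0.05, lfc_cut = 1) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "baseMean",
            "log2FC", "padj")
  if (!all(need %in% names(df)))
    stop("gene table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  if (any(df$start >= df$end)) stop("gene with start >= end")
  validate_coords(df$chrom, df$end, genome, "gene")
  df$status <- de_status(df$log2FC, df$padj, padj_cut, lfc_cut)
  structure(df, class = c("gene_table", "data.frame"))
}

#' @rdname read_gene_table
#' @param genes A `gene_table`.
#' @export
write_gene_table <- function(genes, file) {
  utils::write.table(as.data.frame(genes)[c("gene_id", "chrom", "start", "end",
                                            "strand", "baseMean", "log2FC",
                                            "padj")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

sv_type_map <- c(DEL = "deletion", DUP = "duplication", INV = "inversion",
                 TRA = "translocation-interval", GAIN = "CNV-gain",
                 LOSS = "CNV-loss")

#' Read structural-variant intervals
#'
#' BED-like TSV with header and columns `chrom`, `start`, `end`, `type`;
#' type is one of DEL, DUP, INV, TRA, GAIN, LOSS (or the corresponding long
#' names deletion, duplication, inversion, translocation-interval, CNV-gain,
#' CNV-loss).
#'
#' @param file Path to the TSV.
#' @param genome Optional [genome_spec()] for validation.
#' @return A `sv_set` data.frame with canonical long-form `type`.
#' @export
read_sv_table <- function(file, genome = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "type")
  if (!all(need %in% names(df)))
    stop("SV table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  ty <- df$type
  short <- ty %in% names(sv_type_map)
  ty[short] <- sv_type_map[ty[short]]
  if (!all(ty %in% sv_type_map))
    stop("unknown SV type: ", paste(unique(ty[!ty %in% sv_type_map]),
                                    collapse = ", "))
  df$type <- unname(ty)
  if (any(df$start >= df$end)) stop("SV with start >= end")
  validate_coords(df$chrom, df$end, genome, "SV")
  structure(df, class = c("sv_set", "data.frame"))
}

#' @rdname read_sv_table
#' @param svs A `sv_set`.
#' @export
write_sv_table <- function(svs, file) {
  utils::write.table(as.data.frame(svs), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read whole-genome-sequencing breakpoints
#'
#' TSV with header and columns `chromA`, `posA`, `chromB`, `posB`.
#'
#' @param file Path to the TSV.
#' @param genome Optional [genome_spec()] for validation.
#' @return A `breakpoint_set` data.frame.
#' @export
read_breakpoints <- function(file, genome = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chromA", "posA", "chromB", "posB")
  if (!all(need %in% names(df)))
    stop("breakpoint table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[need]
  validate_coords(df$chromA, df$posA + 1, genome, "breakpoint")
  validate_coords(df$chromB, df$posB + 1, genome, "breakpoint")
  structure(df, class = c("breakpoint_set", "data.frame"))
}

#' @rdname read_breakpoints
#' @param bps A `breakpoint_set`.
#' @export
write_breakpoints <- function(bps, file) {
  utils::write.table(as.data.frame(bps), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

validate_coords <- function(chrom, end, genome, what) {
  if (is.null(genome)) return(invisible(TRUE))
  bad <- !(chrom %in% names(genome))
  if (any(bad))
    stop(what, " on unknown chromosome: ", paste(unique(chrom[bad]), collapse = ", "))
  over <- end > unname(genome[chrom])
  if (any(over))
    stop(what, " coordinate beyond chromosome end (row ", which(over)[1], ")")
  invisible(TRUE)
}
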