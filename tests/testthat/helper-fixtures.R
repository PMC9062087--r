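# shared builders and independent oracles for the test suite

# closed-form Pearson chi-square (no continuity correction) for an r x c
# table; independent of the package's contingency_chisq
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p.value = stats::pchisq(stat, df,
                                                          lower.tail = FALSE))
}

# dense symmetric matrix -> contact_matrix (single- or multi-chromosome bins)
cm_from_dense <- function(bins, mat, kind = "normalized") {
  idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
  contact_matrix(bins, i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                 x = mat[idx], kind = kind)
}

# one-chromosome bin table
bins1 <- function(n, res = 5e4, chrom = "chr1") {
  bin_genome(genome_spec(chrom, n * res), res)
}

# boundary_set from explicit bin indices on a single chromosome
bset <- function(bins, at, strength = 1) {
  structure(
    data.frame(chrom = bins$chrom[at + 1], bin = as.integer(at),
               start = bins$start[at + 1], end = bins$end[at + 1],
               strength = strength, stringsAsFactors = FALSE),
    genome = attr(bins, "genome"), resolution = attr(bins, "resolution"),
    class = c("boundary_set", "data.frame"))
}

# loop_set shorthand from anchor start positions (10 kb anchors)
lset <- function(a1, a2, chrom = "chr1", res = 1e4) {
  loop_set(chrom1 = rep(chrom, length(a1)), start1 = a1, end1 = a1 + res,
           chrom2 = rep(chrom, length(a1)), start2 = a2, end2 = a2 + res)
}

# gene_table rows without file I/O
gtab <- function(chrom, start, end, log2FC = 0, padj = 1, status = NULL) {
  n <- length(start)
  df <- data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
                   start = start, end = end, strand = "+", baseMean = 100,
                   log2FC = log2FC, padj = padj, stringsAsFactors = FALSE)
  df$status <- if (is.null(status)) de_status(df$log2FC, df$padj) else status
  structure(df, class = c("gene_table", "data.frame"))
}
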