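#' Define a genome as an ordered set of chromosomes
#'
#' A `genome_spec` fixes the chromosome universe for all downstream objects:
#' bin tables, contact matrices, loops, SV intervals and gene tables are all
#' validated against it. Chromosome order is the order given here, never
#' lexicographic.
#'
#' @param chroms Character vector of unique chromosome names, in the order
#'   they should appear in binned matrices.
#' @param lengths Numeric vector of chromosome lengths in bp, same length as
#'   `chroms`, all positive.
#' @return An object of class `genome_spec` (named numeric vector of lengths
#'   with class attribute).
#' @examples
#' g <- genome_spec(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_spec <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have the same length")
  if (anyDuplicated(chroms))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(stats::setNames(lengths, chroms), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Tile a genome into fixed-width bins
#'
#' Bins tile each chromosome without gaps or overlap; every bin has width
#' `resolution` except possibly the last bin of each chromosome. Coordinates
#' are 0-based half-open; the global `index` column is dense `0..N-1` in
#' genome order.
#'
#' @param genome A [genome_spec()].
#' @param resolution Bin width in bp (positive).
#' @return A `bin_table`: data.frame with columns `chrom`, `start`, `end`,
#'   `index`, plus attributes `genome` and `resolution`.
#' @examples
#' bins <- bin_genome(genome_spec("chr1", 120), 50)
#' @export
bin_genome <- function(genome, resolution) {
  stopifnot(inherits(genome, "genome_spec"))
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a single positive number")
  pieces <- lapply(names(genome), function(ch) {
    len <- unname(genome[[ch]])
    starts <- seq(0, len - 1, by = resolution)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + resolution, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$index <- seq_len(nrow(bins)) - 1L
  rownames(bins) <- NULL
  structure(bins, genome = genome, resolution = as.numeric(resolution),
            class = c("bin_table", "data.frame"))
}

#' Map genomic positions to global bin indices
#'
#' @param bins A `bin_table` from [bin_genome()].
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos 0-based position(s) in bp; must lie within the chromosome.
#' @return Integer vector of 0-based global bin indices.
#' @export
position_to_bin <- function(bins, chrom, pos) {
  genome <- attr(bins, "genome")
  res <- attr(bins, "resolution")
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  bad <- !(chrom %in% names(genome))
  if (any(bad)) stop("unknown chromosome: ", paste(unique(chrom[bad]), collapse = ", "))
  len <- unname(genome[chrom])
  if (any(pos < 0 | pos >= len))
    stop("position outside chromosome bounds")
  first <- chrom_offsets(bins)[chrom]
  as.integer(first + floor(pos / res))
}

# first global index of each chromosome, named vector
chrom_offsets <- function(bins) {
  off <- tapply(bins$index, bins$chrom, min)
  # tapply sorts by factor level; restore genome order
  genome <- attr(bins, "genome")
  stats::setNames(as.integer(off[names(genome)]), names(genome))
}

# number of bins per chromosome, in genome order
chrom_nbins <- function(bins) {
  tab <- table(bins$chrom)
  genome <- attr(bins, "genome")
  stats::setNames(as.integer(tab[names(genome)]), names(genome))
}

# 1-based row range of a chromosome's bins in the bin table
chrom_bin_range <- function(bins, chrom) {
  idx <- which(bins$chrom == chrom)
  if (!length(idx)) stop("chromosome not in bin table: ", chrom)
  range(idx)
}

same_bins <- function(a, b) {
  isTRUE(all.equal(attr(a, "resolution"), attr(b, "resolution"))) &&
    identical(dim(a), dim(b)) &&
    identical(a$chrom, b$chrom) && identical(a$start, b$start)
}
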