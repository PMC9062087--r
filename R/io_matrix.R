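#' Read a sparse contact matrix in HiC-Pro triplet format
#'
#' The bin file is BED-like with columns (chrom, start, end, 1-based bin id);
#' the matrix file has columns (bin id A, bin id B, value), storing each pair
#' once. Bin ids are 1-based in files and converted to the package's 0-based
#' indices at this boundary. Duplicate (i, j) pairs are an error, not summed:
#' a well-formed HiC-Pro dump lists each pair once, so duplicates indicate
#' upstream corruption.
#'
#' @param matrix_file Path to the triplet matrix file.
#' @param bed_file Path to the bin definition file.
#' @param kind Value kind flag, `"raw"` (default) or `"normalized"`.
#' @return A [contact_matrix()].
#' @export
read_matrix <- function(matrix_file, bed_file, kind = "raw") {
  bins <- read_bins(bed_file)
  n <- nrow(bins)
  lines <- readLines(matrix_file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(contact_matrix(bins, kind = kind))
  parts <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(parts)
  if (any(len != 3))
    stop("malformed matrix line ", which(len != 3)[1], " in ", matrix_file)
  flat <- unlist(parts, use.names = FALSE)
  ii <- suppressWarnings(as.integer(flat[seq(1, length(flat), 3)]))
  jj <- suppressWarnings(as.integer(flat[seq(2, length(flat), 3)]))
  xx <- suppressWarnings(as.numeric(flat[seq(3, length(flat), 3)]))
  bad <- is.na(ii) | is.na(jj) | is.na(xx)
  if (any(bad))
    stop("malformed matrix line ", which(bad)[1], " in ", matrix_file)
  if (any(xx < 0))
    stop("negative value at matrix line ", which(xx < 0)[1], " in ", matrix_file)
  oob <- ii < 1 | ii > n | jj < 1 | jj > n
  if (any(oob))
    stop("unknown bin id at matrix line ", which(oob)[1], " in ", matrix_file)
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  dup <- duplicated(lo * as.numeric(n) + hi)
  if (any(dup))
    stop("duplicate (i, j) entry at matrix line ", which(dup)[1], " in ",
         matrix_file)
  contact_matrix(bins, i = ii - 1L, j = jj - 1L, x = xx, kind = kind)
}

#' @rdname read_matrix
#' @param file Path to a bin definition file.
#' @export
read_bins <- function(file) {
  df <- utils::read.table(file, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "id"),
                          colClasses = c("character", "numeric", "numeric",
                                         "integer"))
  if (!identical(df$id, seq_len(nrow(df))))
    stop("bin ids must be dense 1..N in file order: ", file)
  chroms <- unique(df$chrom)
  lens <- vapply(chroms, function(ch) max(df$end[df$chrom == ch]), numeric(1))
  genome <- genome_spec(chroms, lens)
  res <- df$end[1] - df$start[1]
  bins <- bin_genome(genome, res)
  if (!identical(bins$chrom, df$chrom) || !isTRUE(all.equal(bins$start, df$start)))
    stop("bin file does not tile its genome at a fixed resolution: ", file)
  bins
}

#' Write a contact matrix in HiC-Pro triplet format
#'
#' Stores the upper triangle once with 1-based bin ids, sorted by (i, j);
#' integer values are written without a decimal point so that integer count
#' matrices round-trip byte-exactly.
#'
#' @param m A [contact_matrix()].
#' @param matrix_file,bed_file Output paths.
#' @return Invisibly, the matrix path.
#' @export
write_matrix <- function(m, matrix_file, bed_file) {
  write_bins(m$bins, bed_file)
  tp <- cm_triplets(m)
  tp <- tp[order(tp$i, tp$j), , drop = FALSE]
  xs <- format_num(tp$x)
  writeLines(paste(tp$i, tp$j, xs, sep = "\t"), matrix_file)
  invisible(matrix_file)
}

#' @rdname write_matrix
#' @param bins A `bin_table`.
#' @param file Output path.
#' @export
write_bins <- function(bins, file) {
  writeLines(paste(bins$chrom, format_num(bins$start), format_num(bins$end),
                   bins$index + 1L, sep = "\t"), file)
  invisible(file)
}

# fixed-notation numbers; integers without decimal point
format_num <- function(x) {
  out <- formatC(x, format = "fg", digits = 10, width = 1)
  int <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out[int] <- formatC(x[int], format = "d")
  out
}
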