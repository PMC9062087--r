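#' Construct a binned contact matrix
#'
#' The container used by every analysis stage: a symmetric sparse matrix of
#' non-negative contact values over the bins of a `bin_table`, together with
#' a value-kind flag (`"raw"` counts or `"normalized"`) and a logical mask of
#' excluded bins. The matrix is stored with both triangles filled so that
#' marginals and block extraction are plain matrix operations; symmetry is an
#' enforced invariant, and on-disk formats store the upper triangle once.
#'
#' @param bins A `bin_table` from [bin_genome()].
#' @param i,j 0-based global bin indices of entries (any orientation).
#' @param x Non-negative values, same length as `i`.
#' @param kind `"raw"` or `"normalized"`.
#' @param mask Optional logical vector (length = number of bins) of excluded
#'   bins; defaults to all `FALSE`.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, i = integer(), j = integer(), x = numeric(),
                           kind = c("raw", "normalized"), mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(bins, "bin_table"))
  n <- nrow(bins)
  if (length(i) != length(j) || length(i) != length(x))
    stop("i, j, x must have equal length")
  if (length(x) && (any(!is.finite(x)) || any(x < 0)))
    stop("contact values must be finite and non-negative")
  if (length(i) && (any(i < 0) || any(i >= n) || any(j < 0) || any(j >= n)))
    stop("bin index out of range")
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- lo * n + hi
  if (anyDuplicated(key))
    stop("duplicate (i, j) entries")
  off <- lo != hi
  mat <- Matrix::sparseMatrix(
    i = c(lo, hi[off]) + 1L, j = c(hi, lo[off]) + 1L, x = c(x, x[off]),
    dims = c(n, n))
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(is.logical(mask), length(mask) == n)
  new_contact_matrix(bins, mat, kind, mask)
}

new_contact_matrix <- function(bins, mat, kind, mask,
                               masked_blocks = list()) {
  structure(list(bins = bins, mat = methods::as(mat, "CsparseMatrix"),
                 kind = kind, mask = mask, masked_blocks = masked_blocks),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins @ %s bp (%s), %d stored entries, %d masked bins\n",
              nrow(x$bins), format(attr(x$bins, "resolution"), big.mark = ","),
              x$kind, Matrix::nnzero(x$mat), sum(x$mask)))
  invisible(x)
}

#' Look up contact values by bin index
#'
#' @param m A `contact_matrix`.
#' @param i,j 0-based global bin indices (vectors recycled).
#' @return Numeric vector of values; symmetric by construction.
#' @export
cm_lookup <- function(m, i, j) {
  n <- max(length(i), length(j))
  i <- rep_len(as.integer(i), n); j <- rep_len(as.integer(j), n)
  m$mat[cbind(i + 1L, j + 1L)]
}

#' Extract a dense chromosome-pair block
#'
#' @param m A `contact_matrix`.
#' @param chrom_a,chrom_b Chromosome names; equal for a cis block.
#' @return Dense base matrix of the block, rows = bins of `chrom_a`.
#' @export
cm_block <- function(m, chrom_a, chrom_b = chrom_a) {
  ra <- chrom_bin_range(m$bins, chrom_a)
  rb <- chrom_bin_range(m$bins, chrom_b)
  as.matrix(m$mat[ra[1]:ra[2], rb[1]:rb[2], drop = FALSE])
}

# logical mask restricted to one chromosome
cm_block_mask <- function(m, chrom) {
  r <- chrom_bin_range(m$bins, chrom)
  m$mask[r[1]:r[2]]
}

#' Per-bin marginal sums
#'
#' Row sums of the symmetric matrix; masked bins return `NA`.
#' @param m A `contact_matrix`.
#' @param na_masked Replace masked-bin marginals with `NA` (default `TRUE`).
#' @return Numeric vector, one value per bin.
#' @export
cm_marginals <- function(m, na_masked = TRUE) {
  s <- Matrix::rowSums(m$mat)
  if (na_masked) s[m$mask] <- NA_real_
  s
}

#' Apply a bin mask to a contact matrix
#'
#' Zeroes all entries touching a masked bin so that no unmasked entry refers
#' to a masked bin, and records the mask.
#' @param m A `contact_matrix`.
#' @param mask Logical vector over bins; combined (OR) with any prior mask.
#' @return Masked `contact_matrix`.
#' @export
cm_apply_mask <- function(m, mask) {
  stopifnot(length(mask) == nrow(m$bins))
  mask <- mask | m$mask
  mat <- m$mat
  if (any(mask)) {
    keep <- Matrix::Diagonal(x = as.numeric(!mask))
    mat <- keep %*% mat %*% keep
    mat <- Matrix::drop0(mat)
  }
  new_contact_matrix(m$bins, mat, m$kind, mask, m$masked_blocks)
}

# upper-triangle triplet view: data.frame(i, j, x) with 1-based i <= j
cm_triplets <- function(m) {
  t3 <- methods::as(Matrix::triu(m$mat), "TsparseMatrix")
  keep <- t3@x != 0
  data.frame(i = t3@i[keep] + 1L, j = t3@j[keep] + 1L, x = t3@x[keep])
}

# total cis and trans sums over the upper triangle (diagonal counted once)
cm_cis_trans_totals <- function(m) {
  tp <- cm_triplets(m)
  if (!nrow(tp)) return(c(cis = 0, trans = 0))
  same <- m$bins$chrom[tp$i] == m$bins$chrom[tp$j]
  c(cis = sum(tp$x[same]), trans = sum(tp$x[!same]))
}
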