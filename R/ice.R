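#' ICE matrix balancing
#'
#' Iterative correction: removes multiplicative per-bin bias by rescaling the
#' matrix until all unmasked marginals are equal. Bins with zero coverage, or
#' with coverage below the `coverage_filter_fraction` quantile of nonzero
#' marginals, are masked before balancing (HiC-Pro-like behavior). Each
#' iteration divides entry (i, j) by `delta_i * delta_j` where `delta_i` is
#' the bin's marginal relative to the mean marginal, accumulating the deltas
#' into the returned bias vector; convergence is declared when the
#' coefficient of variation of the unmasked marginals drops below `tol`.
#'
#' @param m A raw [contact_matrix()].
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on the marginal CV (default 1e-5).
#' @param coverage_filter_fraction Quantile of nonzero marginals below which
#'   bins are masked (default 0.02).
#' @return A list with elements `matrix` (normalized `contact_matrix`),
#'   `bias` (per-bin multiplicative bias, `NA` for masked bins), `mask`,
#'   `converged` and `iterations`.
#' @examples
#' bins <- bin_genome(genome_spec("chr1", 400), 100)
#' m <- contact_matrix(bins, i = c(0, 1, 2), j = c(1, 2, 3), x = c(4, 4, 4))
#' ice_normalize(m)$converged
#' @export
ice_normalize <- function(m, max_iter = 200, tol = 1e-5,
                          coverage_filter_fraction = 0.02) {
  stopifnot(max_iter >= 1, tol > 0)
  s0 <- Matrix::rowSums(m$mat)
  if (any(!is.finite(s0))) stop("non-finite values in matrix")
  nz <- s0[s0 > 0 & !m$mask]
  cutoff <- if (length(nz)) stats::quantile(nz, coverage_filter_fraction) else Inf
  mask <- m$mask | s0 <= 0 | s0 < cutoff
  if (all(mask)) stop("all bins masked during coverage filtering")
  mm <- cm_apply_mask(m, mask)
  mat <- mm$mat
  un <- which(!mask)
  bias <- rep(NA_real_, nrow(m$bins))
  bias[un] <- 1
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    s <- Matrix::rowSums(mat)[un]
    mu <- mean(s)
    if (mu <= 0) stop("balancing degenerated to an all-zero matrix")
    if (sqrt(stats::var(s)) / mu < tol) { converged <- TRUE; break }
    delta <- rep(1, nrow(m$bins))
    delta[un] <- s / mu
    dinv <- Matrix::Diagonal(x = 1 / delta)
    mat <- dinv %*% mat %*% dinv
    bias[un] <- bias[un] * delta[un]
  }
  out <- new_contact_matrix(m$bins, Matrix::drop0(mat), "normalized", mask,
                            m$masked_blocks)
  list(matrix = out, bias = bias, mask = mask,
       converged = converged, iterations = iter)
}
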