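# Second-order random-walk smooths on binned covariates.

#' Second-difference penalty of a random-walk smooth
#'
#' Structure matrix `t(D) %*% D` of the second-order random walk on
#' `n_bins` ordered bins: rank `n_bins - 2`, null space spanned by the
#' constant and linear sequences. A sum-to-zero constraint is applied at fit
#' time, not here.
#'
#' @param n_bins number of bins (>= 5).
#' @return Sparse symmetric penalty matrix.
#' @export
rw2_precision <- function(n_bins) {
  if (!is_one_number(n_bins) || n_bins < 5) stop_fmt("n_bins must be >= 5")
  n_bins <- as.integer(n_bins)
  D <- matrix(0, n_bins - 2L, n_bins)
  for (i in seq_len(n_bins - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1)
  Matrix::drop0(Matrix::forceSymmetric(crossprod(D)))
}

#' Discretise a covariate into equal-width bins
#'
#' @param values finite numeric covariate values.
#' @param n_bins number of equal-width bins over the observed range (>= 5).
#' @return Integer bin index per observation (`min -> 1`, `max -> n_bins`),
#'   with the bin midpoints in `attr(, "midpoints")` and the break points in
#'   `attr(, "breaks")`.
#' @export
bin_covariate <- function(values, n_bins = 20L) {
  if (any(!is.finite(values))) stop_fmt("non-finite covariate values")
  if (!is_one_number(n_bins) || n_bins < 5) stop_fmt("n_bins must be >= 5")
  r <- range(values)
  if (r[1] == r[2]) stop_fmt("constant covariate cannot be binned")
  n_bins <- as.integer(n_bins)
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(values, breaks, all.inside = TRUE), 1L), n_bins)
  attr(idx, "midpoints") <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  attr(idx, "breaks") <- breaks
  idx
}
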