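# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a base seed and a label
#'
#' Every stochastic generator in the package draws its randomness from a
#' substream keyed by a short label, so adding a new generator never perturbs
#' the output of existing ones under the same base seed.
#'
#' @param seed integer base seed.
#' @param label character label of the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(42, "cores") != substream_seed(42, "environment")
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147480009)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# column-wise logsumexp of a matrix
col_logsumexp <- function(m) {
  mx <- apply(m, 2L, max)
  mx + log(colSums(exp(sweep(m, 2L, mx))))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

is_one_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
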