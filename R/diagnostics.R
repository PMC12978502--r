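# Model assessment: WAIC from the pointwise log-likelihood matrix,
# importance-weighted leave-one-out predictive checks, and the probability
# integral transform.

#' Watanabe-Akaike information criterion
#'
#' `waic = -2 (lppd - p_waic)`, with the log pointwise predictive density
#' `lppd = sum_i log mean_s p(y_i | draw s)` and the effective number of
#' parameters `p_waic = sum_i var_s log p(y_i | draw s)`, both computed from
#' the stored draw-by-observation log-likelihood matrix.
#'
#' @param fit a `reef_fit` (or a raw draws-by-observations log-likelihood
#'   matrix).
#' @return List with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(fit) {
  ll <- if (inherits(fit, "reef_fit")) fit$loglik else as.matrix(fit)
  if (is.null(ll) || nrow(ll) < 2L) stop_fmt("need >= 2 posterior draws for WAIC")
  S <- nrow(ll)
  lppd <- sum(col_logsumexp(ll) - log(S))
  p_waic <- sum(apply(ll, 2L, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Rank candidate fits by WAIC
#'
#' @param ... named `reef_fit` objects (or a single list of them).
#' @return Data frame sorted by ascending WAIC (best first).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "reef_fit")) {
    fits <- fits[[1]]
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  w <- lapply(fits, waic)
  out <- data.frame(model = names(fits),
                    waic = vapply(w, `[[`, 0, "waic"),
                    lppd = vapply(w, `[[`, 0, "lppd"),
                    p_waic = vapply(w, `[[`, 0, "p_waic"))
  out <- out[order(out$waic), ]
  rownames(out) <- NULL
  out
}

#' Leave-one-out probability integral transform
#'
#' For each observation, leave-one-out predictive draws are approximated by
#' importance weighting the posterior draws with the reciprocal of that
#' observation's likelihood (truncated at `sqrt(S)` times the mean weight to
#' stabilise the heaviest tails). The PIT value is the importance-weighted
#' predictive CDF at the observation; under a calibrated model the PIT values
#' are uniform, summarised by a Kolmogorov-Smirnov distance.
#'
#' @param fit a `reef_fit` with stored log-likelihood draws.
#' @return List with `pit` (one value per observation in `[0, 1]`),
#'   `ks_stat`, `ks_p`, and `flagged` (observations whose importance weights
#'   have effective sample size below S/10).
#' @export
pit_loo <- function(fit) {
  stopifnot(inherits(fit, "reef_fit"))
  if (is.null(fit$loglik)) stop_fmt("fit holds no data")
  ll <- fit$loglik                      # S x n
  S <- nrow(ll); n <- ncol(ll)
  etas <- as.matrix(fit$B %*% fit$draws)  # n x S
  alpha <- fit$shape_draws %||% rep(fit$shape, S)
  pit <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    lw <- -ll[, i]
    lw <- lw - logsumexp(lw)
    w <- exp(lw)
    w <- pmin(w, sqrt(S) * mean(w))     # truncated importance weights
    w <- w / sum(w)
    flagged[i] <- (1 / sum(w^2)) < S / 10
    cdf <- pgamma(fit$y[i], shape = alpha, rate = alpha * exp(-etas[i, ]))
    pit[i] <- sum(w * cdf)
  }
  ks <- suppressWarnings(ks.test(pit, "punif"))
  list(pit = pit, ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       flagged = flagged)
}
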