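# Hierarchical Bayesian gamma model for reef growth rates.
#
# log-mean = fixed effects + second-order random-walk smooths on binned
# covariates + iid group effects + a Matern (SPDE) spatial field. All latent
# effects are jointly Gaussian given the hyperparameters, so the posterior is
# computed by an empirical-Bayes nested-Laplace scheme: an inner Newton
# iteration gives the Gaussian approximation of the latent field at fixed
# hyperparameters, the Laplace-approximate marginal likelihood is maximised
# over the (low-dimensional) hyperparameters, and posterior draws of the
# latent field are taken from the Gaussian approximation at the mode. The
# contract is statistical (recovery and calibration on data simulated from
# the model), not algorithmic identity with any particular software.

#' Prior settings of the growth model
#'
#' Weakly-informative defaults in the penalised-complexity spirit: fixed
#' effects (on standardised covariates) get independent normal priors;
#' random-effect standard deviations get exponential priors shrinking toward
#' zero; the spatial field gets an inverse-range prior discouraging ranges
#' far below `range0` and an exponential prior on its marginal standard
#' deviation; the gamma shape gets a flat-rate gamma prior.
#'
#' @param beta_sd prior sd of the non-intercept fixed effects (standardised
#'   scale), default 1.
#' @param intercept_sd prior sd of the intercept, default 10.
#' @param sd_lambda exponential rate for iid and random-walk effect sds
#'   (default 2.3, i.e. prior mass 0.1 above sd 1).
#' @param spatial_sigma_lambda exponential rate for the field marginal sd.
#' @param spatial_range0 median of the field-range prior; defaults to 30% of
#'   the site extent at fit time.
#' @param rw2_mean_sd prior sd of a smooth's overall level (a tight value
#'   acts as a soft sum-to-zero constraint), default 0.1.
#' @param shape_rate rate of the exponential prior on the gamma shape.
#' @return List of prior settings, class `reef_priors`.
#' @export
reef_priors <- function(beta_sd = 1, intercept_sd = 10, sd_lambda = 2.3,
                        spatial_sigma_lambda = 2.3, spatial_range0 = NULL,
                        rw2_mean_sd = 0.1, shape_rate = 0.1) {
  structure(list(beta_sd = beta_sd, intercept_sd = intercept_sd,
                 sd_lambda = sd_lambda,
                 spatial_sigma_lambda = spatial_sigma_lambda,
                 spatial_range0 = spatial_range0,
                 rw2_mean_sd = rw2_mean_sd, shape_rate = shape_rate),
            class = "reef_priors")
}

# ---- formula parsing --------------------------------------------------------

# Model terms: plain names are fixed effects; rw2(x, bins) adds a
# second-order random-walk smooth of the binned covariate; iid(g) adds an
# exchangeable group effect; spde(lon, lat) adds the spatial field.
.parse_growth_formula <- function(formula) {
  tf <- terms(formula)
  labels <- attr(tf, "term.labels")
  out <- list(response = deparse(formula[[2]]), fixed = character(0),
              rw2 = list(), iid = character(0), spde = NULL,
              intercept = attr(tf, "intercept") == 1)
  for (lab in labels) {
    if (grepl("^rw2\\(", lab)) {
      cl <- str2lang(lab)
      bins <- if (!is.null(cl$bins)) cl$bins else if (length(cl) >= 3 && is.null(cl$bins)) cl[[3]] else 20L
      out$rw2[[length(out$rw2) + 1L]] <-
        list(var = deparse(cl[[2]]), bins = as.integer(eval(bins)))
    } else if (grepl("^iid\\(", lab)) {
      cl <- str2lang(lab)
      out$iid <- c(out$iid, deparse(cl[[2]]))
    } else if (grepl("^spde\\(", lab)) {
      cl <- str2lang(lab)
      out$spde <- list(lon = deparse(cl[[2]]), lat = deparse(cl[[3]]))
    } else {
      out$fixed <- c(out$fixed, lab)
    }
  }
  both <- intersect(out$fixed, vapply(out$rw2, `[[`, "", "var"))
  if (length(both)) {
    stop_fmt("covariate(s) %s appear both as fixed effects and smooths",
             paste(both, collapse = ", "))
  }
  out
}

# ---- prior precision --------------------------------------------------------

# Assemble the block-diagonal latent prior precision at hyperparameters
# theta. Blocks: fixed effects, one per rw2 smooth, one per iid group, the
# spatial field.
.prior_precision <- function(blocks, theta, priors) {
  parts <- lapply(blocks, function(b) {
    switch(b$type,
      fixed = Matrix::Diagonal(b$size, 1 / b$prior_sd^2),
      rw2 = {
        tau <- exp(theta[[b$theta]])
        m <- b$size
        J <- Matrix::Matrix(1 / m^2 / priors$rw2_mean_sd^2, m, m)
        Matrix::forceSymmetric(tau * b$R + J + Matrix::Diagonal(m, 1e-6))
      },
      iid = exp(theta[[b$theta]]) * Matrix::Diagonal(b$size),
      spde = spde_precision(b$fem, exp(theta[["logkappa"]]),
                            exp(theta[["logtau_s"]]))
    )
  })
  Matrix::forceSymmetric(Matrix::bdiag(parts))
}

# log prior density of the hyperparameters (on their log scales)
.theta_logprior <- function(theta, blocks, priors, range0) {
  lp <- 0
  for (b in blocks) {
    if (b$type %in% c("rw2", "iid")) {
      sig <- exp(-theta[[b$theta]] / 2)
      lp <- lp + log(priors$sd_lambda) - priors$sd_lambda * sig + log(sig / 2)
    }
  }
  if ("logkappa" %in% names(theta)) {
    rho <- sqrt(8) / exp(theta[["logkappa"]])
    lam_r <- -log(0.5) * range0
    lp <- lp + log(lam_r) - 2 * log(rho) - lam_r / rho + log(rho)
    sig_s <- 1 / (sqrt(4 * pi) * exp(theta[["logkappa"]]) * exp(theta[["logtau_s"]]))
    lp <- lp + log(priors$spatial_sigma_lambda) -
      priors$spatial_sigma_lambda * sig_s + log(sig_s)
  }
  alpha <- exp(theta[["logshape"]])
  lp <- lp + log(priors$shape_rate) - priors$shape_rate * alpha + log(alpha)
  lp
}

# log-determinant of a sparse SPD matrix
.sp_logdet <- function(M) {
  as.numeric(Matrix::determinant(Matrix::forceSymmetric(M), logarithm = TRUE)$modulus)
}

# gamma log-likelihood at linear predictor eta (log link)
.gamma_ll <- function(y, eta, alpha) {
  sum(alpha * log(alpha) - lgamma(alpha) + (alpha - 1) * log(y) -
        alpha * eta - alpha * y * exp(-eta))
}

# Inner Newton iteration: Gaussian approximation of the latent posterior at
# fixed hyperparameters. Returns mode, Cholesky of the negative Hessian, and
# the pieces of the Laplace marginal likelihood.
.latent_laplace <- function(y, B, Qp, alpha, x0 = NULL, max_iter = 60L) {
  d <- ncol(B)
  x <- x0 %||% numeric(d)
  obj <- function(x, eta) .gamma_ll(y, eta, alpha) - 0.5 * sum(x * as.numeric(Qp %*% x))
  eta <- as.numeric(B %*% x)
  f <- obj(x, eta)
  converged <- FALSE
  H <- NULL
  for (it in seq_len(max_iter)) {
    w <- alpha * y * exp(-pmax(pmin(eta, 40), -40))  # clamp guards overflow
    g <- w - alpha
    Bs <- Matrix::Diagonal(length(y), sqrt(w)) %*% B
    H <- Matrix::forceSymmetric(Qp + Matrix::crossprod(Bs))
    grad <- as.numeric(Matrix::crossprod(B, g)) - as.numeric(Qp %*% x)
    ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
    delta <- as.numeric(Matrix::solve(ch, grad))
    step <- 1
    repeat {
      x_new <- x + step * delta
      eta_new <- as.numeric(B %*% x_new)
      f_new <- obj(x_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { x_new <- x; eta_new <- eta; f_new <- f; break }
    }
    moved <- max(abs(x_new - x))
    x <- x_new; eta <- eta_new; f <- f_new
    if (moved < 1e-8 * (1 + max(abs(x)))) { converged <- TRUE; break }
  }
  w <- alpha * y * exp(-pmax(pmin(eta, 40), -40))
  Bs <- Matrix::Diagonal(length(y), sqrt(w)) %*% B
  H <- Matrix::forceSymmetric(Qp + Matrix::crossprod(Bs))
  ch <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
  list(x = x, eta = eta, ll = .gamma_ll(y, eta, alpha),
       quad = 0.5 * sum(x * as.numeric(Qp %*% x)),
       chol = ch, logdet_H = .sp_logdet(H), converged = converged)
}

# Draw from N(mean, H^{-1}) given the Cholesky factorisation of H.
.draw_gaussian <- function(ch, mean, n) {
  d <- length(mean)
  z <- matrix(rnorm(d * n), d, n)
  y <- Matrix::solve(ch, z, system = "Lt")
  as.matrix(Matrix::solve(ch, y, system = "Pt")) + mean
}

# ---- the fit ----------------------------------------------------------------

#' Fit the hierarchical Bayesian gamma growth model
#'
#' The model for a positive response \eqn{y_i} (growth rate, mm/yr) is
#' \deqn{y_i \sim \mathrm{Gamma}(\alpha, \alpha/\mu_i), \quad
#'       \log \mu_i = \beta_0 + x_i^\top\beta + \sum_k f_k(c_{ki}) +
#'       \sum_g u_{g[i]} + s(\mathrm{loc}_i),}
#' with fixed effects \eqn{\beta} on z-scored covariates, second-order
#' random-walk smooths \eqn{f_k} on binned covariates, iid group effects
#' \eqn{u}, and a Matern spatial field \eqn{s} represented on a triangular
#' mesh. Terms are declared in the formula:
#' `rate ~ sl_rate + sst + volc + rw2(co2, bins = 20) + iid(region) +
#' spde(lon, lat)`.
#'
#' @param formula model formula; plain terms become fixed effects,
#'   `rw2(x, bins)` random-walk smooths, `iid(g)` exchangeable group
#'   effects, and `spde(lon, lat)` the spatial field.
#' @param data data frame holding the response and covariates (complete
#'   cases only; non-finite values are an error). May have zero rows, in
#'   which case the posterior equals the prior at the initial
#'   hyperparameters.
#' @param priors a [reef_priors()] object.
#' @param mesh optional pre-built [build_mesh()] mesh (planar, matching
#'   [project_coords()] of the site coordinates); built automatically
#'   otherwise.
#' @param n_draws posterior draws of the latent field (default 1000).
#' @param seed integer seed (drives the posterior sampling).
#' @param hyper `"integrate"` (default) propagates hyperparameter
#'   uncertainty by drawing hyperparameters from a Gaussian approximation of
#'   their posterior (numerical Hessian at the mode) and mixing the latent
#'   Gaussian approximations over those draws; `"plugin"` conditions on the
#'   posterior mode of the hyperparameters.
#' @param n_theta number of hyperparameter draws in `"integrate"` mode.
#' @param verbose print progress from the hyperparameter optimiser.
#' @return An object of class `reef_fit`; see [summary.reef_fit()],
#'   [classify_effect()], [waic()], [pit_loo()].
#' @export
reef_fit <- function(formula, data, priors = reef_priors(), mesh = NULL,
                     n_draws = 1000L, seed = 1L,
                     hyper = c("integrate", "plugin"), n_theta = 16L,
                     verbose = FALSE) {
  hyper <- match.arg(hyper)
  spec <- .parse_growth_formula(formula)
  data <- as.data.frame(data)
  n <- nrow(data)
  y <- if (n > 0) data[[spec$response]] else numeric(0)
  if (n > 0) {
    used <- c(spec$response, spec$fixed, vapply(spec$rw2, `[[`, "", "var"))
    for (v in used) {
      if (is.null(data[[v]])) stop_fmt("column '%s' not found", v)
      if (any(!is.finite(data[[v]]))) {
        stop_fmt("non-finite values in '%s' (rows %s)", v,
                 paste(head(which(!is.finite(data[[v]])), 5), collapse = ", "))
      }
    }
    if (any(y <= 0)) stop_fmt("gamma response must be positive")
  }

  # latent blocks and design ---------------------------------------------
  blocks <- list()
  Bparts <- list()
  scaling <- list()
  p_fixed <- 1L + length(spec$fixed)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in spec$fixed) {
    mu <- mean(data[[v]]); sdv <- sd(data[[v]])
    if (n == 0) { mu <- 0; sdv <- 1 }
    if (sdv == 0) stop_fmt("fixed-effect covariate '%s' is constant", v)
    scaling[[v]] <- c(mean = mu, sd = sdv)
    X <- cbind(X, (data[[v]] - mu) / sdv)
    colnames(X)[ncol(X)] <- v
  }
  blocks[[1]] <- list(name = "fixed", type = "fixed", size = p_fixed,
                      prior_sd = c(priors$intercept_sd,
                                   rep(priors$beta_sd, length(spec$fixed))),
                      labels = colnames(X))
  Bparts[[1]] <- Matrix::Matrix(X, sparse = TRUE)

  for (k in seq_along(spec$rw2)) {
    v <- spec$rw2[[k]]$var; m <- spec$rw2[[k]]$bins
    idx <- if (n > 0) bin_covariate(data[[v]], m) else
      structure(integer(0), midpoints = seq_len(m), breaks = seq_len(m + 1))
    A <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(idx), x = 1,
                              dims = c(n, m))
    blocks[[length(blocks) + 1L]] <-
      list(name = paste0("rw2_", v), type = "rw2", size = m,
           theta = paste0("logtau_rw2_", v), R = rw2_precision(m),
           var = v, midpoints = attr(idx, "midpoints"),
           breaks = attr(idx, "breaks"),
           labels = paste0(v, "[", seq_len(m), "]"))
    Bparts[[length(Bparts) + 1L]] <- A
  }
  for (v in spec$iid) {
    if (n > 0 && is.null(data[[v]])) stop_fmt("grouping column '%s' not found", v)
    f <- factor(if (n > 0) data[[v]] else character(0))
    m <- max(1L, nlevels(f))
    A <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f), x = 1,
                              dims = c(n, m))
    blocks[[length(blocks) + 1L]] <-
      list(name = paste0("iid_", v), type = "iid", size = m,
           theta = paste0("logtau_iid_", v), var = v,
           labels = paste0(v, ":", if (nlevels(f)) levels(f) else "1"))
    Bparts[[length(Bparts) + 1L]] <- A
  }
  extent <- 1
  if (!is.null(spec$spde)) {
    coords <- project_coords(data[[spec$spde$lon]], data[[spec$spde$lat]])
    extent <- max(apply(coords, 2, function(z) diff(range(z))), 1e-6)
    if (is.null(mesh)) {
      mesh <- build_mesh(coords, fine_edge = extent / 12,
                         coarse_edge = extent / 4, buffer = extent / 3,
                         seed = seed)
    }
    A <- mesh_project(mesh, coords)
    fem <- fem_matrices(mesh)
    blocks[[length(blocks) + 1L]] <-
      list(name = "spatial", type = "spde", size = fem$n, fem = fem,
           mesh = mesh, labels = paste0("s[", seq_len(fem$n), "]"))
    Bparts[[length(Bparts) + 1L]] <- A
  }
  B <- do.call(cbind, Bparts)
  d <- ncol(B)
  offs <- cumsum(c(0, vapply(blocks, `[[`, 0, "size")))
  for (k in seq_along(blocks)) blocks[[k]]$idx <- (offs[k] + 1L):offs[k + 1L]

  # hyperparameters -------------------------------------------------------
  theta <- c()
  for (b in blocks) if (b$type %in% c("rw2", "iid")) theta[b$theta] <- log(16)
  if (!is.null(spec$spde)) {
    range0 <- priors$spatial_range0 %||% (0.3 * extent)
    kappa0 <- sqrt(8) / range0
    theta["logkappa"] <- log(kappa0)
    theta["logtau_s"] <- log(1 / (sqrt(4 * pi) * kappa0 * 0.5))
  } else range0 <- 1
  alpha0 <- if (n > 1) max(0.5, min(50, mean(y)^2 / var(y))) else 2
  theta["logshape"] <- log(alpha0)

  state <- new.env(parent = emptyenv())
  state$x0 <- NULL
  negml <- function(th) {
    names(th) <- names(theta)
    Qp <- .prior_precision(blocks, th, priors)
    if (n == 0) return(-.theta_logprior(th, blocks, priors, range0))
    lap <- .latent_laplace(y, B, Qp, exp(th[["logshape"]]), x0 = state$x0)
    state$x0 <- lap$x
    ml <- lap$ll - lap$quad + 0.5 * .sp_logdet(Qp) - 0.5 * lap$logdet_H +
      .theta_logprior(th, blocks, priors, range0)
    if (!is.finite(ml)) return(1e10)
    -ml
  }
  conv_hyper <- TRUE
  if (n > 0 && length(theta) > 0) {
    ctl <- list(iter.max = 200, eval.max = 400,
                trace = if (verbose) 1 else 0, rel.tol = 1e-7)
    opt <- nlminb(theta, negml, control = ctl)
    clean <- function(o) o$convergence == 0 ||
      grepl("relative convergence|both X|singular convergence", o$message %||% "")
    if (!clean(opt)) {
      # restart once from the stopped point; "false convergence" usually
      # resolves after the inner warm starts settle
      opt2 <- nlminb(opt$par, negml, control = ctl)
      if (opt2$objective <= opt$objective) opt <- opt2
    }
    theta_hat <- setNames(opt$par, names(theta))
    conv_hyper <- clean(opt)
  } else theta_hat <- theta

  alpha_hat <- exp(theta_hat[["logshape"]])
  Qp <- .prior_precision(blocks, theta_hat, priors)
  if (n > 0) {
    lap <- .latent_laplace(y, B, Qp, alpha_hat, x0 = state$x0)
  } else {
    ch <- Matrix::Cholesky(Qp, LDL = FALSE, perm = TRUE)
    lap <- list(x = numeric(d), eta = numeric(0), chol = ch, converged = TRUE)
  }

  set.seed(substream_seed(seed, "posterior-draws"))
  theta_draws <- NULL
  if (hyper == "integrate" && n > 0 && length(theta) > 0) {
    Hth <- tryCatch(stats::optimHess(theta_hat, negml), error = function(e) NULL)
    if (!is.null(Hth) && all(is.finite(Hth))) {
      Hth <- (Hth + t(Hth)) / 2
      eg <- eigen(Hth, symmetric = TRUE)
      ev <- pmax(eg$values, 1e-4)
      # sd scale of theta posterior: H^{-1/2}
      half <- eg$vectors %*% diag(1 / sqrt(ev), length(ev)) %*% t(eg$vectors)
      theta_draws <- t(theta_hat + half %*%
                         matrix(rnorm(length(theta_hat) * n_theta),
                                length(theta_hat)))
      colnames(theta_draws) <- names(theta_hat)
    }
  }

  if (is.null(theta_draws)) {
    draws <- .draw_gaussian(lap$chol, lap$x, n_draws)
    shape_draws <- rep(alpha_hat, n_draws)
  } else {
    per <- diff(round(seq(0, n_draws, length.out = n_theta + 1L)))
    draws <- matrix(NA_real_, d, n_draws)
    shape_draws <- numeric(n_draws)
    at <- 0L
    x_warm <- lap$x
    for (s in seq_len(n_theta)) {
      if (per[s] == 0L) next
      th <- setNames(theta_draws[s, ], names(theta_hat))
      Qs <- .prior_precision(blocks, th, priors)
      ls <- .latent_laplace(y, B, Qs, exp(th[["logshape"]]), x0 = x_warm,
                            max_iter = 50L)
      cols <- at + seq_len(per[s])
      draws[, cols] <- .draw_gaussian(ls$chol, ls$x, per[s])
      shape_draws[cols] <- exp(th[["logshape"]])
      at <- at + per[s]
    }
  }
  rownames(draws) <- unlist(lapply(blocks, `[[`, "labels"))

  loglik <- NULL
  if (n > 0) {
    etas <- as.matrix(B %*% draws)             # n x S
    a_long <- rep(shape_draws, each = n)
    loglik <- t(matrix(dgamma(rep(y, times = n_draws), shape = a_long,
                              rate = a_long * exp(-as.numeric(etas)),
                              log = TRUE), nrow = n))  # S x n
  }

  out <- structure(list(
    call = match.call(), formula = formula, spec = spec, blocks = blocks,
    B = B, y = y, data = data, n = n, scaling = scaling,
    priors = priors, theta = theta_hat, shape = alpha_hat,
    shape_draws = if (n > 0) shape_draws else rep(alpha_hat, n_draws),
    mode = lap$x, draws = draws, loglik = loglik, mesh = mesh,
    flags = list(hyper_converged = conv_hyper,
                 inner_converged = isTRUE(lap$converged)),
    seed = seed), class = "reef_fit")
  if (!conv_hyper || !isTRUE(lap$converged)) {
    warning("inference flagged as not fully converged; see $flags", call. = FALSE)
  }
  out
}

# Locate a latent element by label or a block by name.
.block_by_name <- function(fit, name) {
  for (b in fit$blocks) if (b$name == name || identical(b$var %||% "", name)) return(b)
  NULL
}

#' Posterior draws of one model term
#'
#' @param fit a `reef_fit`.
#' @param term a fixed-effect name (e.g. `"sl_rate"`), `"(Intercept)"`, or a
#'   latent label such as `"region:Asia"`.
#' @param scale for fixed effects, `"standardised"` (per sd of the
#'   covariate; default) or `"raw"` (per original covariate unit).
#' @return Numeric vector of posterior draws.
#' @export
term_draws <- function(fit, term, scale = c("standardised", "raw")) {
  scale <- match.arg(scale)
  lab <- rownames(fit$draws)
  if (!term %in% lab) stop_fmt("term '%s' not in the model", term)
  dr <- fit$draws[term, ]
  if (scale == "raw" && term %in% names(fit$scaling)) {
    dr <- dr / fit$scaling[[term]][["sd"]]
  }
  dr
}

#' Classify a coefficient by its credible interval
#'
#' A term is credible-positive (negative) at a level when the corresponding
#' equal-tailed credible interval excludes zero from below (above), and
#' not-credible otherwise.
#'
#' @param x a `reef_fit` (with `term`) or a numeric vector of posterior
#'   draws.
#' @param term term name when `x` is a fit.
#' @param level credible level (default 0.8).
#' @return One of `"credible-positive"`, `"credible-negative"`,
#'   `"not-credible"`.
#' @export
classify_effect <- function(x, term = NULL, level = 0.8) {
  draws <- if (inherits(x, "reef_fit")) term_draws(x, term) else as.numeric(x)
  a <- (1 - level) / 2
  ci <- quantile(draws, c(a, 1 - a), names = FALSE)
  if (ci[1] > 0) "credible-positive"
  else if (ci[2] < 0) "credible-negative"
  else "not-credible"
}

#' Posterior effect curve of a random-walk smooth
#'
#' @param fit a `reef_fit`.
#' @param var the smoothed covariate name.
#' @param probs quantiles of the pointwise band.
#' @return Data frame with the bin midpoints, posterior mean effect, and
#'   pointwise quantiles.
#' @export
effect_curve <- function(fit, var, probs = c(0.05, 0.95)) {
  b <- .block_by_name(fit, paste0("rw2_", var)) %||% .block_by_name(fit, var)
  if (is.null(b) || b$type != "rw2") stop_fmt("no rw2 smooth on '%s'", var)
  dr <- fit$draws[b$idx, , drop = FALSE]
  qs <- t(apply(dr, 1, quantile, probs = probs, names = FALSE))
  out <- data.frame(value = b$midpoints, mean = rowMeans(dr))
  for (j in seq_along(probs)) out[[paste0("q", probs[j] * 100)]] <- qs[, j]
  out
}

# ---- methods ----------------------------------------------------------------

#' @export
print.reef_fit <- function(x, ...) {
  cat("Hierarchical gamma growth model (log link)\n")
  cat("  observations:", x$n, "\n")
  cat("  fixed effects:", paste(x$spec$fixed, collapse = ", ") , "\n")
  if (length(x$spec$rw2)) {
    cat("  rw2 smooths:",
        paste(vapply(x$spec$rw2, function(r) sprintf("%s(%d bins)", r$var, r$bins), ""),
              collapse = ", "), "\n")
  }
  if (length(x$spec$iid)) cat("  iid groups:", paste(x$spec$iid, collapse = ", "), "\n")
  if (!is.null(x$spec$spde)) cat("  spatial field: on (", nrow(x$mesh$loc), "mesh nodes )\n")
  cat("  gamma shape:", signif(x$shape, 4), "\n")
  if (!all(unlist(x$flags))) cat("  NOTE: inference flagged; see $flags\n")
  invisible(x)
}

#' Posterior summary of a growth-model fit
#'
#' @param object a `reef_fit`.
#' @param hyper include hyperparameters in the printout.
#' @param ... unused.
#' @return Data frame of posterior means, sds, and 50/80/90% interval
#'   endpoints for the fixed effects and smooth/group levels.
#' @export
summary.reef_fit <- function(object, hyper = TRUE, ...) {
  probs <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
  keep <- unlist(lapply(object$blocks, function(b)
    if (b$type %in% c("fixed", "rw2", "iid")) b$idx else NULL))
  dr <- object$draws[keep, , drop = FALSE]
  qs <- t(apply(dr, 1, quantile, probs = probs, names = FALSE))
  colnames(qs) <- paste0("q", probs * 100)
  out <- data.frame(term = rownames(dr), mean = rowMeans(dr),
                    sd = apply(dr, 1, sd), qs, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "shape") <- object$shape
  attr(out, "theta") <- object$theta
  class(out) <- c("summary.reef_fit", "data.frame")
  out
}

#' @export
print.summary.reef_fit <- function(x, ...) {
  cat("Posterior summary (gamma growth model)\n")
  df <- as.data.frame(x)
  print(format(head(df, 30), digits = 3), row.names = FALSE)
  if (nrow(df) > 30) cat("  ...", nrow(df) - 30, "more latent terms\n")
  cat("gamma shape:", signif(attr(x, "shape"), 4), "\n")
  invisible(x)
}

#' @export
coef.reef_fit <- function(object, scale = c("standardised", "raw"), ...) {
  scale <- match.arg(scale)
  b <- .block_by_name(object, "fixed")
  cf <- rowMeans(object$draws[b$idx, , drop = FALSE])
  names(cf) <- b$labels
  if (scale == "raw") {
    for (v in names(object$scaling)) cf[v] <- cf[v] / object$scaling[[v]][["sd"]]
  }
  cf
}

#' Posterior fitted values or predictions
#'
#' @param object a `reef_fit`.
#' @param newdata optional data frame with the model covariates (and
#'   coordinates when a spatial term is present). Defaults to the training
#'   data.
#' @param type `"link"` for the linear predictor, `"response"` for the
#'   posterior mean growth rate.
#' @param ... unused.
#' @return Numeric vector of posterior-mean predictions.
#' @export
predict.reef_fit <- function(object, newdata = NULL, type = c("response", "link"), ...) {
  type <- match.arg(type)
  B <- if (is.null(newdata)) object$B else .build_design(object, newdata)
  etas <- as.matrix(B %*% object$draws)
  if (type == "link") rowMeans(etas) else rowMeans(exp(etas))
}

# Rebuild the sparse design for new data, using the stored scalings, bin
# breaks, and group levels. Unseen group levels get a zero effect.
.build_design <- function(fit, newdata) {
  n <- nrow(newdata)
  parts <- list()
  for (b in fit$blocks) {
    parts[[length(parts) + 1L]] <- switch(b$type,
      fixed = {
        X <- matrix(1, n, 1)
        for (v in fit$spec$fixed) {
          sc <- fit$scaling[[v]]
          X <- cbind(X, (newdata[[v]] - sc[["mean"]]) / sc[["sd"]])
        }
        Matrix::Matrix(X, sparse = TRUE)
      },
      rw2 = {
        idx <- pmin(pmax(findInterval(newdata[[b$var]], b$breaks,
                                      all.inside = TRUE), 1L), b$size)
        Matrix::sparseMatrix(i = seq_len(n), j = idx, x = 1, dims = c(n, b$size))
      },
      iid = {
        lev <- sub(paste0("^", b$var, ":"), "", b$labels)
        j <- match(as.character(newdata[[b$var]]), lev)
        ok <- !is.na(j)
        Matrix::sparseMatrix(i = which(ok), j = j[ok], x = 1, dims = c(n, b$size))
      },
      spde = {
        coords <- project_coords(newdata[[fit$spec$spde$lon]],
                                 newdata[[fit$spec$spde$lat]])
        mesh_project(b$mesh, coords)
      })
  }
  do.call(cbind, parts)
}

#' @export
residuals.reef_fit <- function(object, type = c("quantile", "deviance"), ...) {
  type <- match.arg(type)
  eta <- rowMeans(as.matrix(object$B %*% object$draws))
  mu <- exp(eta)
  if (type == "quantile") {
    qnorm(pgamma(object$y, shape = object$shape, rate = object$shape / mu))
  } else {
    r <- object$y / mu
    sign(object$y - mu) * sqrt(2 * object$shape * (r - 1 - log(r)))
  }
}

#' @export
simulate.reef_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- ncol(object$draws)
  out <- matrix(NA_real_, object$n, nsim)
  for (j in seq_len(nsim)) {
    s <- sample.int(S, 1L)
    mu <- exp(as.numeric(object$B %*% object$draws[, s]))
    a <- object$shape_draws[s]
    out[, j] <- rgamma(object$n, shape = a, rate = a / mu)
  }
  as.data.frame(out)
}

#' @export
plot.reef_fit <- function(x, which = c("fixed", "smooths"), ...) {
  which <- match.arg(which)
  if (which == "fixed") {
    b <- .block_by_name(x, "fixed")
    idx <- b$idx[-1]  # drop intercept
    if (!length(idx)) return(invisible(x))
    dr <- x$draws[idx, , drop = FALSE]
    qs <- apply(dr, 1, quantile, probs = c(0.05, 0.1, 0.25, 0.75, 0.9, 0.95))
    m <- rowMeans(dr)
    k <- length(m)
    plot(m, seq_len(k), xlim = range(qs), ylim = c(0.5, k + 0.5), yaxt = "n",
         xlab = "posterior coefficient (per sd)", ylab = "", pch = 19, ...)
    axis(2, at = seq_len(k), labels = b$labels[-1], las = 1)
    segments(qs[1, ], seq_len(k), qs[6, ], seq_len(k), lwd = 1)
    segments(qs[2, ], seq_len(k), qs[5, ], seq_len(k), lwd = 2.5)
    segments(qs[3, ], seq_len(k), qs[4, ], seq_len(k), lwd = 4)
    abline(v = 0, lty = 2)
  } else {
    vars <- vapply(x$spec$rw2, `[[`, "", "var")
    if (!length(vars)) return(invisible(x))
    old <- par(mfrow = c(1, length(vars))); on.exit(par(old))
    for (v in vars) {
      ec <- effect_curve(x, v)
      plot(ec$value, ec$mean, type = "l", xlab = v, ylab = "effect (log scale)",
           ylim = range(ec[, -1]), ...)
      polygon(c(ec$value, rev(ec$value)), c(ec[[3]], rev(ec[[4]])),
              col = adjustcolor("grey", 0.5), border = NA)
      lines(ec$value, ec$mean, lwd = 2)
      abline(h = 0, lty = 2)
    }
  }
  invisible(x)
}

#' @importFrom graphics axis
NULL
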