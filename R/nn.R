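# Feed-forward network for nonlinear growth responses: seeded data splits,
# a small multilayer perceptron trained by Adam with early stopping, a
# restart/selection protocol keyed to validation RMSE, and partial-dependence
# curves. The network is written in plain matrix algebra: rectified hidden
# units, squared-error loss, inputs z-scored internally, predictions
# returned on the original mm/yr scale.

#' Network training configuration
#'
#' Defaults mirror the study protocol: two hidden layers of 20 and 10
#' rectified units, up to 100 epochs with early stopping after 5 rounds
#' without validation improvement, a 70/15/15 train/test/validation split,
#' and 30 restarts selected by validation root mean-squared error.
#'
#' @param hidden integer vector of hidden-layer sizes.
#' @param epochs maximum training epochs.
#' @param patience early-stopping rounds (epochs without validation
#'   improvement).
#' @param fractions train/test/validation fractions (must sum to 1).
#' @param restarts number of random restarts (>= 1).
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param candidates optional list of alternative `hidden` architectures to
#'   screen alongside the default (the selected architecture is reported).
#' @param seed integer seed.
#' @return A list of class `nn_config`.
#' @export
nn_config <- function(hidden = c(20L, 10L), epochs = 100L, patience = 5L,
                      fractions = c(train = 0.70, test = 0.15, validation = 0.15),
                      restarts = 30L, lr = 0.01, batch = 32L,
                      candidates = NULL, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop_fmt("split fractions must sum to 1")
  if (restarts < 1L) stop_fmt("restarts must be >= 1")
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 patience = as.integer(patience), fractions = fractions,
                 restarts = as.integer(restarts), lr = lr,
                 batch = as.integer(batch), candidates = candidates,
                 seed = as.integer(seed)), class = "nn_config")
}

#' Candidate network architectures
#'
#' A documented screening list of six configurations (hidden-layer layouts),
#' including the final two-layer 20/10 architecture.
#'
#' @return List of integer vectors.
#' @export
nn_candidates <- function() {
  list(c(20L, 10L), c(10L, 5L), c(30L, 15L), c(20L), c(40L), c(10L, 10L))
}

#' Seeded train/test/validation split
#'
#' Disjoint, exhaustive, seeded shuffle with split sizes within one unit of
#' the requested fractions.
#'
#' @param n number of records (>= 20), or a data frame whose rows are split.
#' @param fractions named train/test/validation fractions summing to 1.
#' @param seed integer seed.
#' @return List with integer index vectors `train`, `test`, `validation`.
#' @export
split_data <- function(n, fractions = c(train = 0.70, test = 0.15, validation = 0.15),
                       seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (abs(sum(fractions) - 1) > 1e-8) stop_fmt("split fractions must sum to 1")
  if (n < 20L) stop_fmt("need at least 20 records to split")
  set.seed(substream_seed(seed, "split"))
  idx <- sample.int(n)
  n_train <- round(fractions[[1]] * n)
  n_test <- round(fractions[[2]] * n)
  list(train = sort(idx[seq_len(n_train)]),
       test = sort(idx[n_train + seq_len(n_test)]),
       validation = sort(idx[(n_train + n_test + 1):n]))
}

# He-style initialisation of one weight matrix
.init_layer <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

.forward <- function(layers, X) {
  acts <- list(X)
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% layers[[l]]$W + rep(layers[[l]]$b, each = nrow(X))
    acts[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
  }
  acts
}

# One Adam update from a mini-batch; returns updated layers and moments.
.adam_step <- function(layers, mstate, X, y, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  L <- length(layers)
  acts <- .forward(layers, X)
  nb <- nrow(X)
  delta <- 2 * (acts[[L + 1]] - y) / nb         # d loss / d output
  for (l in L:1) {
    gW <- crossprod(acts[[l]], delta)
    gb <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
    }
    for (nm in c("W", "b")) {
      g <- if (nm == "W") gW else gb
      mstate[[l]][[nm]]$m <- beta1 * mstate[[l]][[nm]]$m + (1 - beta1) * g
      mstate[[l]][[nm]]$v <- beta2 * mstate[[l]][[nm]]$v + (1 - beta2) * g^2
      mhat <- mstate[[l]][[nm]]$m / (1 - beta1^t)
      vhat <- mstate[[l]][[nm]]$v / (1 - beta2^t)
      layers[[l]][[nm]] <- layers[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, mstate = mstate)
}

# Train one network on (X, y) with early stopping on a validation set.
# X, y are already standardised; returns layers and the validation RMSE
# (on the standardised response scale of the caller's choosing).
.train_mlp <- function(X, y, Xval, yval, hidden, epochs, patience, lr, batch,
                       seed) {
  set.seed(seed)
  sizes <- c(ncol(X), hidden, 1L)
  layers <- lapply(seq_len(length(sizes) - 1L),
                   function(l) .init_layer(sizes[l], sizes[l + 1]))
  mstate <- lapply(layers, function(ly) list(
    W = list(m = ly$W * 0, v = ly$W * 0),
    b = list(m = ly$b * 0, v = ly$b * 0)))
  n <- nrow(X)
  best <- list(rmse = Inf, layers = layers)
  stall <- 0L
  t <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      take <- ord[start:min(start + batch - 1L, n)]
      t <- t + 1
      upd <- .adam_step(layers, mstate, X[take, , drop = FALSE],
                        y[take, , drop = FALSE], lr, t)
      layers <- upd$layers; mstate <- upd$mstate
    }
    pv <- .forward(layers, Xval)[[length(layers) + 1]]
    rmse <- sqrt(mean((pv - yval)^2))
    if (rmse < best$rmse - 1e-9) {
      best <- list(rmse = rmse, layers = layers)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  best
}

#' Train the growth-response network with restarts and select the best run
#'
#' Splits the data, trains `restarts` seeded runs (per candidate
#' architecture, when a candidate list is supplied), each with early
#' stopping monitored on the validation split, and returns the run with the
#' lowest validation root mean-squared error together with the full RMSE
#' table.
#'
#' @param data data frame with the response in `response` and the predictor
#'   columns in `inputs`.
#' @param config an [nn_config()].
#' @param response response column (default `"rate"`, mm/yr).
#' @param inputs predictor columns (default SST, rate of sea-level change,
#'   absolute latitude).
#' @return Object of class `reef_nn`: the selected network (with input and
#'   output scalings), the per-run validation RMSE table, and the split
#'   indices.
#' @export
nn_train_select <- function(data, config = nn_config(), response = "rate",
                            inputs = c("sst", "sl_rate", "abs_latitude")) {
  data <- as.data.frame(data)
  for (v in c(response, inputs)) {
    if (is.null(data[[v]])) stop_fmt("column '%s' not found", v)
    if (any(!is.finite(data[[v]]))) stop_fmt("non-finite values in '%s'", v)
  }
  sp <- split_data(nrow(data), config$fractions, seed = config$seed)
  X <- as.matrix(data[inputs])
  y <- matrix(data[[response]], ncol = 1)
  xm <- colMeans(X[sp$train, , drop = FALSE])
  xs <- apply(X[sp$train, , drop = FALSE], 2, sd)
  xs[xs == 0] <- 1
  ym <- mean(y[sp$train, ]); ys <- sd(y[sp$train, ]); if (ys == 0) ys <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ysc <- (y - ym) / ys

  archs <- c(list(config$hidden), config$candidates)
  runs <- list(); tab <- NULL
  for (a in seq_along(archs)) {
    for (r in seq_len(config$restarts)) {
      run_seed <- substream_seed(config$seed, sprintf("nn-a%d-r%d", a, r))
      fit <- .train_mlp(Xs[sp$train, , drop = FALSE], ysc[sp$train, , drop = FALSE],
                        Xs[sp$validation, , drop = FALSE],
                        ysc[sp$validation, , drop = FALSE],
                        archs[[a]], config$epochs, config$patience,
                        config$lr, config$batch, run_seed)
      runs[[length(runs) + 1L]] <- fit
      tab <- rbind(tab, data.frame(
        architecture = paste(archs[[a]], collapse = "-"), run = r,
        val_rmse = fit$rmse * ys))
    }
  }
  best_i <- which.min(tab$val_rmse)
  best <- runs[[best_i]]
  test_pred <- .forward(best$layers, Xs[sp$test, , drop = FALSE])[[length(best$layers) + 1]]
  structure(list(layers = best$layers, inputs = inputs, response = response,
                 x_center = xm, x_scale = xs, y_center = ym, y_scale = ys,
                 rmse_table = tab, best = tab[best_i, ],
                 val_rmse = tab$val_rmse[best_i],
                 test_rmse = sqrt(mean((test_pred * ys + ym - y[sp$test, ])^2)),
                 split = sp, config = config), class = "reef_nn")
}

#' @export
predict.reef_nn <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[object$inputs])
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  out <- .forward(object$layers, Xs)[[length(object$layers) + 1]]
  as.numeric(out) * object$y_scale + object$y_center
}

#' @export
print.reef_nn <- function(x, ...) {
  cat("Feed-forward growth-response network\n")
  cat("  architecture:", x$best$architecture, " (selected of",
      nrow(x$rmse_table), "runs)\n")
  cat("  validation RMSE:", signif(x$val_rmse, 4), " test RMSE:",
      signif(x$test_rmse, 4), "\n")
  invisible(x)
}

#' Partial-dependence curve of one network input
#'
#' For each grid value the input is set to that value for every record, the
#' network predictions are averaged, and the observed distribution of the
#' input is recorded as a histogram.
#'
#' @param model a `reef_nn`.
#' @param data data frame of records over which predictions are averaged.
#' @param variable one of the model inputs.
#' @param grid evaluation grid; defaults to 50 points spanning the observed
#'   range of the variable.
#' @return Object of class `reef_pdp` with `variable`, `grid`, `mean_pred`,
#'   and the histogram of the observed variable.
#' @export
partial_dependence <- function(model, data, variable, grid = NULL) {
  if (!variable %in% model$inputs) stop_fmt("'%s' is not a model input", variable)
  data <- as.data.frame(data)
  obs <- data[[variable]]
  if (is.null(grid)) grid <- seq(min(obs), max(obs), length.out = 50L)
  if (length(grid) == 0L) stop_fmt("empty partial-dependence grid")
  if (any(grid < min(obs) - 1e-9) || any(grid > max(obs) + 1e-9)) {
    stop_fmt("grid extends beyond the observed range of '%s'", variable)
  }
  mp <- vapply(grid, function(g) {
    d <- data; d[[variable]] <- g
    mean(predict(model, d))
  }, numeric(1))
  structure(list(variable = variable, grid = grid, mean_pred = mp,
                 histogram = hist(obs, plot = FALSE)), class = "reef_pdp")
}

#' @export
plot.reef_pdp <- function(x, ...) {
  old <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1)); on.exit(par(old))
  plot(x$grid, x$mean_pred, type = "l", lwd = 2, xlab = x$variable,
       ylab = "mean predicted rate (mm/yr)", ...)
  plot(x$histogram, main = "", xlab = x$variable, col = "grey")
  invisible(x)
}
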