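# The hierarchical gamma model: moment recovery, prior behaviour, WAIC,
# PIT calibration, and effect classification.

test_that("an intercept-only gamma fit recovers the sample mean", {
  set.seed(31)
  y <- rgamma(5000, shape = 4, rate = 4 / 2.5)
  fit <- reef_fit(rate ~ 1, data.frame(rate = y), n_draws = 500, seed = 1,
                  hyper = "plugin")
  mu_hat <- exp(mean(term_draws(fit, "(Intercept)")))
  expect_lt(abs(mu_hat - mean(y)) / mean(y), 0.02)
  expect_lt(abs(fit$shape - 4) / 4, 0.15)
})

test_that("with no data the posterior reproduces the prior", {
  fit <- reef_fit(rate ~ 1, data.frame(rate = numeric(0)), n_draws = 4000,
                  seed = 2)
  dr <- term_draws(fit, "(Intercept)")
  expect_lt(abs(mean(dr)), 0.5)
  expect_lt(abs(sd(dr) - fit$priors$intercept_sd) / fit$priors$intercept_sd, 0.1)
})

test_that("input validation catches bad responses and term clashes", {
  d <- data.frame(rate = c(1, 2, -1), x = 1:3)
  expect_error(reef_fit(rate ~ x, d), "positive")
  d2 <- data.frame(rate = c(1, 2, 3), x = c(1, NA, 3))
  expect_error(reef_fit(rate ~ x, d2), "non-finite")
  d3 <- data.frame(rate = rlnorm(20), x = rnorm(20))
  expect_error(reef_fit(rate ~ x + rw2(x, 5), d3), "both")
  expect_error(reef_fit(rate ~ z, d3), "not found")
})

test_that("WAIC matches the brute-force definition and is additive", {
  set.seed(32)
  y <- rgamma(80, 3, 3 / 2)
  fit <- reef_fit(rate ~ 1, data.frame(rate = y), n_draws = 400, seed = 3,
                  hyper = "plugin")
  w <- waic(fit)
  ll <- fit$loglik
  S <- nrow(ll)
  lppd <- 0; p <- 0
  for (i in seq_len(ncol(ll))) {
    lppd <- lppd + log(mean(exp(ll[, i])))
    p <- p + var(ll[, i])
  }
  expect_equal(w$waic, -2 * (lppd - p), tolerance = 1e-9)
  # duplicating every observation doubles the lppd contributions
  w2 <- waic(cbind(ll, ll))
  expect_equal(w2$lppd, 2 * w$lppd, tolerance = 1e-9)
  expect_error(waic(ll[1, , drop = FALSE]), ">= 2")
})

test_that("effect classification follows the stated interval logic", {
  up <- qnorm(seq(0.0005, 0.9995, length.out = 2000), mean = 0.3, sd = 0.11)
  expect_equal(classify_effect(up, level = 0.8), "credible-positive")
  wide <- qnorm(seq(0.0005, 0.9995, length.out = 2000), mean = 0.05, sd = 0.2)
  expect_equal(classify_effect(wide, level = 0.8), "not-credible")
  sym <- c(-rev(seq(0.001, 1, 0.001)), seq(0.001, 1, 0.001))
  for (lv in c(0.5, 0.8, 0.9)) {
    expect_equal(classify_effect(sym, level = lv), "not-credible")
  }
  expect_equal(classify_effect(-up, level = 0.8), "credible-negative")
})

test_that("raw-scale draws are the standardised draws over the covariate sd", {
  set.seed(33)
  d <- data.frame(rate = rlnorm(200), x = rnorm(200, sd = 3))
  fit <- reef_fit(rate ~ x, d, n_draws = 300, seed = 4, hyper = "plugin")
  expect_equal(term_draws(fit, "x", "raw"),
               term_draws(fit, "x") / sd(d$x), tolerance = 1e-12)
})

test_that("PIT values are uniform under a correctly specified model", {
  pvals <- numeric(20)
  for (s in 1:20) {
    set.seed(600 + s)
    n <- 200
    x <- rnorm(n)
    y <- rgamma(n, 5, 5 / exp(0.4 + 0.5 * x))
    fit <- reef_fit(rate ~ x, data.frame(rate = y, x = x), n_draws = 400,
                    seed = s, hyper = "plugin")
    p <- pit_loo(fit)
    pvals[s] <- p$ks_p
    expect_true(all(p$pit >= 0 & p$pit <= 1))
  }
  expect_gte(sum(pvals > 0.01), 18)  # >=90% of seeds look calibrated
})

test_that("PIT detects a missing strong covariate", {
  hits <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    n <- 250
    x <- rnorm(n)
    y <- rgamma(n, 8, 8 / exp(0.3 + 1.2 * x))
    fit <- reef_fit(rate ~ 1, data.frame(rate = y, x = x), n_draws = 400,
                    seed = s, hyper = "plugin")
    hits <- hits + (pit_loo(fit)$ks_p < 0.01)
  }
  expect_gte(hits, 6)  # non-uniform PIT in most seeds
})

test_that("credible intervals nest and summaries expose the latent terms", {
  set.seed(34)
  d <- data.frame(rate = rlnorm(150), x = rnorm(150), g = sample(letters[1:4], 150, TRUE))
  fit <- reef_fit(rate ~ x + iid(g), d, n_draws = 500, seed = 5, hyper = "plugin")
  s <- summary(fit)
  expect_true(all(c("term", "mean", "sd", "q5", "q10", "q25", "q50",
                    "q75", "q90", "q95") %in% names(s)))
  expect_true(all(s$q10 <= s$q25 & s$q25 <= s$q50 &
                    s$q50 <= s$q75 & s$q75 <= s$q90))
  expect_true(any(grepl("^g:", s$term)))
  expect_equal(length(coef(fit)), 2L)
})

test_that("prediction, simulation and residuals behave on a well-fit model", {
  set.seed(35)
  n <- 400
  x <- rnorm(n)
  y <- rgamma(n, 6, 6 / exp(0.5 + 0.8 * x))
  d <- data.frame(rate = y, x = x)
  fit <- reef_fit(rate ~ x, d, n_draws = 400, seed = 6, hyper = "plugin")
  mu <- predict(fit)
  expect_gt(cor(mu, y), 0.6)
  expect_equal(length(predict(fit, newdata = d[1:7, ])), 7L)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(n, 3L))
  expect_true(all(sims > 0))
  r <- residuals(fit)
  expect_lt(abs(sd(r) - 1), 0.25)   # quantile residuals roughly standard normal
})
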