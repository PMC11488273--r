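test_that("profiled-ML fit matches lme4 on a small unbalanced dataset", {
  skip_if_not_installed("lme4")
  set.seed(101)
  g <- rep(1:5, times = c(1, 2, 3, 3, 4))
  d <- data.frame(participant_id = g,
                  time_days = ave(g, g, FUN = function(v) seq_along(v) - 1) * 30,
                  x = rnorm(length(g)))
  d$y <- 2 + 0.02 * d$time_days + 0.5 * d$x + rnorm(5)[g] + rnorm(nrow(d), 0, 0.5)
  fit <- fit_lmm(d, y ~ time_days + x)
  m <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ time_days + x + (1 | participant_id), d, REML = FALSE)
  ))
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(lme4::fixef(m)), tolerance = 1e-5)
})

test_that("with no between-participant variance the fit collapses to OLS", {
  set.seed(11)
  d <- simulate_lmm(40, beta = c(1, -0.01), sigma2_b = 0, sigma2_e = 1)
  fit <- fit_lmm(d, y ~ time_days)
  ols <- stats::lm(y ~ time_days, d)
  if (fit$boundary) {
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
    expect_equal(fit$sigma2_b, 0)
  }
  # profiled deviance at lambda = 0 always equals the OLS Gaussian loglik
  X <- stats::model.matrix(~time_days, d)
  f0 <- edoutcomes:::lmm_profile_fit(X, d$y, factor(d$participant_id))
  n <- nrow(d)
  rss <- sum(stats::residuals(ols)^2)
  ll_ols <- -0.5 * (n * log(2 * pi * rss / n) + n)
  if (f0$boundary) expect_equal(f0$loglik, ll_ols, tolerance = 1e-8)
})

test_that("profiled deviance is unimodal over a lambda grid on toy data", {
  set.seed(5)
  d <- simulate_lmm(30, beta = c(2, -0.02), sigma2_b = 1, sigma2_e = 0.25)
  X <- stats::model.matrix(~time_days, d)
  g <- factor(d$participant_id)
  ni <- as.numeric(table(g))
  lls <- vapply(exp(seq(-6, 6, length.out = 80)), function(lam) {
    # re-derive the profiled loglik directly (independent of the optimizer)
    ci <- lam / (1 + lam * ni)
    Sx <- rowsum(X, g); Sy <- rowsum(d$y, g)[, 1]
    XtVX <- crossprod(X) - crossprod(Sx, ci * Sx)
    XtVy <- crossprod(X, d$y) - crossprod(Sx, ci * Sy)
    beta <- solve(XtVX, XtVy)
    rss <- sum(d$y^2) - sum(ci * Sy^2) - 2 * sum(beta * XtVy) +
      sum(beta * (XtVX %*% beta))
    -0.5 * (nrow(d) * log(2 * pi * rss / nrow(d)) + sum(log1p(lam * ni)) + nrow(d))
  }, numeric(1))
  # single interior maximum: sign of the discrete slope changes at most once
  s <- sign(diff(lls))
  expect_lte(sum(diff(s[s != 0]) != 0), 1)
  # and the fitted optimum is at least as good as the best grid point
  fit <- fit_lmm(d, y ~ time_days)
  expect_gte(fit$loglik + 1e-8, max(lls))
})

test_that("fixed effects are recovered across replicated simulations", {
  set.seed(202)
  truth <- c(2, -0.02)
  reps <- 40
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    d <- simulate_lmm(200, beta = truth, sigma2_b = 1, sigma2_e = 0.25)
    f <- fit_lmm(d, y ~ time_days)
    est[r, ] <- f$beta
  }
  se_mean <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(colMeans(est) - truth) < 3 * se_mean))
})

test_that("partial_r2 follows the F-statistic algebra and its invariances", {
  set.seed(33)
  d <- simulate_lmm(80, beta = c(1, -0.03), sigma2_b = 0.8, sigma2_e = 0.3)
  d$between_x <- rep(rnorm(80), each = 3)
  fit <- fit_lmm(d, y ~ time_days + between_x)
  r2_time <- partial_r2(fit, "time_days", boot = 0)
  # within-participant term: containment denominator dof
  expect_equal(r2_time$df2, fit$n_obs - ncol(fit$X) - (fit$n_groups - 1))
  expect_equal(r2_time$partial_r2,
               r2_time$df1 * r2_time$F / (r2_time$df1 * r2_time$F + r2_time$df2))
  # between-participant term: denominator from the between design
  r2_b <- partial_r2(fit, "between_x", boot = 0)
  expect_equal(r2_b$df2, fit$n_groups - 2)  # intercept + between_x
  # invariance to outcome rescaling
  d10 <- d; d10$y <- 10 * d10$y
  fit10 <- fit_lmm(d10, y ~ time_days + between_x)
  expect_equal(partial_r2(fit10, "time_days", boot = 0)$partial_r2,
               r2_time$partial_r2, tolerance = 1e-6)
  expect_gte(r2_time$partial_r2, 0)
  expect_lte(r2_time$partial_r2, 1)
  # bootstrap interval brackets a strong effect away from zero
  ci <- partial_r2(fit, "time_days", boot = 50, seed = 4)
  expect_true(ci$conf.low <= ci$partial_r2 && ci$partial_r2 <= ci$conf.high)
  expect_error(partial_r2(fit, "nope"), "not in the model")
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(2)
  d <- simulate_lmm(30, beta = c(1, -0.02), sigma2_b = 1, sigma2_e = 0.25)
  fit <- fit_lmm(d, y ~ time_days)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "time_days"))
  expect_true(all(c("estimate", "std.error", "statistic", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_groups, 30)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("fit_lmm validates its inputs", {
  d <- simulate_lmm(5, beta = c(1, 0), sigma2_b = 1, sigma2_e = 1)
  expect_error(fit_lmm(d, y ~ nope), "not in data")
  d$dup <- d$time_days
  expect_error(fit_lmm(d, y ~ time_days + dup), "rank deficient")
  expect_error(fit_lmm(d[d$participant_id == 1, ], y ~ time_days),
               "2 participants")
  # available-case: rows with missing outcome are dropped, not fatal
  d$y[1] <- NA
  f <- fit_lmm(d, y ~ time_days)
  expect_equal(f$n_obs, 14)
  expect_equal(f$n_dropped, 1)
})
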