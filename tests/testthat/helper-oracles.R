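# Independent oracles used to cross-check package computations.

# Cronbach's alpha straight from the population covariance matrix:
# alpha = k/(k-1) * (1 - tr(C) / sum(C)).
alpha_covmat_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  C <- stats::cov(x) * (n - 1) / n  # population denominator
  k <- ncol(x)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# Marginal NB-GLMM log-likelihood by adaptive Gauss-Hermite quadrature,
# written independently of the package's Laplace path (1-D mode search via
# optimize, curvature by finite differences).
agq_loglik_nb <- function(beta, sigma2_b, theta, X, y, g, nodes = 31) {
  gh <- pracma::gaussHermite(nodes)
  eta <- drop(X %*% beta)
  total <- 0
  for (lev in unique(g)) {
    i <- g == lev
    f <- function(b) {
      sum(stats::dnbinom(y[i], size = theta, mu = exp(eta[i] + b), log = TRUE)) -
        b^2 / (2 * sigma2_b) - 0.5 * log(2 * pi * sigma2_b)
    }
    bhat <- stats::optimize(function(b) -f(b), c(-20, 20))$minimum
    h <- 1e-4
    H <- -(f(bhat + h) - 2 * f(bhat) + f(bhat - h)) / h^2
    s <- sqrt(1 / H)
    vals <- vapply(gh$x, function(z) f(bhat + sqrt(2) * s * z) + z^2, numeric(1))
    m <- max(vals)
    total <- total + log(sum(gh$w * exp(vals - m))) + m + 0.5 * log(2) + log(s)
  }
  total
}

# Simulate from the random-intercept Gaussian model.
simulate_lmm <- function(n_groups, times = c(0, 40, 80), beta,
                         sigma2_b, sigma2_e, X_extra = NULL) {
  g <- rep(seq_len(n_groups), each = length(times))
  t <- rep(times, n_groups)
  X <- cbind(1, t)
  if (!is.null(X_extra)) X <- cbind(X, X_extra)
  b <- stats::rnorm(n_groups, 0, sqrt(sigma2_b))
  y <- drop(X %*% beta) + b[g] + stats::rnorm(length(g), 0, sqrt(sigma2_e))
  data.frame(participant_id = g, time_days = t, y = y)
}
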