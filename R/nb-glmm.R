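#' Fit a random-intercept negative-binomial mixed model (Laplace)
#'
#' Negative-binomial regression with a log link and a participant-level
#' random intercept, for over-dispersed counts such as binge-eating or
#' vomiting episode frequencies. The NB2 parameterization is used: given the
#' conditional mean \eqn{\mu}, the variance is \eqn{\mu + \mu^2/\theta}.
#' The marginal likelihood integrates the random intercept out per
#' participant; the integral is approximated by the Laplace method (an inner
#' Newton iteration finds the conditional mode of each participant's random
#' effect, and the integrand's curvature at the mode supplies the Gaussian
#' correction). The outer optimization runs BFGS over
#' \eqn{(\beta, \log\sigma^2_b, \log\theta)} so both variance parameters stay
#' positive.
#'
#' @param data A data frame in long format.
#' @param formula Fixed-effects formula; the response must be nonnegative
#'   integer counts.
#' @param group Name of the grouping (participant id) column.
#' @param control List: `inner_tol` (inner-mode gradient tolerance, default
#'   1e-9), `inner_maxit` (default 50), `outer_maxit` (default 500),
#'   `grad_tol` (outer gradient infinity-norm tolerance, default 1e-4 on the
#'   scaled problem).
#' @return An object of class `nb_glmm_fit`: `beta` (log scale) with SEs and
#'   Wald tests, `sigma2_b`, `theta`, `loglik`, random-effect modes, and
#'   sample sizes.
#' @export
fit_nb_glmm <- function(data, formula, group = "participant_id",
                        control = list()) {
  ctrl <- utils::modifyList(list(inner_tol = 1e-9, inner_maxit = 50L,
                                 outer_maxit = 500L, grad_tol = 1e-4), control)
  stopifnot(is.data.frame(data), inherits(formula, "formula"))
  vars <- all.vars(formula)
  keep <- stats::complete.cases(data[vars]) & !is.na(data[[group]])
  d <- data[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != round(y))) {
    stop("outcome must be nonnegative integer counts", call. = FALSE)
  }
  if (all(y == 0)) stop("all counts are zero: degenerate data", call. = FALSE)
  g <- factor(d[[group]])
  if (qr(X)$rank < ncol(X)) stop("design is rank deficient", call. = FALSE)
  gi <- as.integer(g)
  ng <- nlevels(g)
  p <- ncol(X)

  # Inner problem: conditional mode of b given (beta, sigma2_b, theta).
  # d/db log NB(y | mu = exp(eta + b)) = theta (y - mu) / (theta + mu);
  # d2/db2 = -theta mu (theta + y) / (theta + mu)^2. Newton, vectorized
  # over participants, with step halving.
  inner_modes <- function(eta, s2b, theta, b) {
    # exponent clamp keeps the objective finite while the outer optimizer
    # explores extreme parameter values
    mu_of <- function(b) exp(pmin(eta + b[gi], 30))
    pen_obj <- function(b) {
      v <- rowsum(stats::dnbinom(y, size = theta, mu = mu_of(b), log = TRUE),
                  gi)[, 1L] - b^2 / (2 * s2b)
      v[!is.finite(v)] <- -1e15  # keep step-halving comparisons well defined
      v
    }
    obj <- pen_obj(b)
    for (it in seq_len(ctrl$inner_maxit)) {
      mu <- mu_of(b)
      grad <- rowsum(theta * (y - mu) / (theta + mu), gi)[, 1L] - b / s2b
      hess <- -rowsum(theta * mu * (theta + y) / (theta + mu)^2, gi)[, 1L] - 1 / s2b
      if (!all(is.finite(grad)) || !all(is.finite(hess))) {
        return(list(b = b, loglik = -Inf))
      }
      if (max(abs(grad)) < ctrl$inner_tol) break
      step <- -grad / hess
      # step halving on participants whose penalized objective worsened
      for (h in 0:30) {
        cand <- b + step
        obj_new <- pen_obj(cand)
        worse <- obj_new < obj - 1e-8
        if (!any(worse)) break
        step[worse] <- step[worse] / 2
      }
      if (any(worse)) break  # no ascent possible beyond numerical noise
      b <- cand
      obj <- obj_new
    }
    mu <- mu_of(b)
    H <- rowsum(theta * mu * (theta + y) / (theta + mu)^2, gi)[, 1L] + 1 / s2b
    ll <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE)) -
      sum(b^2) / (2 * s2b) - ng / 2 * log(s2b) - 0.5 * sum(log(H))
    list(b = b, loglik = ll)
  }

  b_cache <- numeric(ng)
  nll <- function(par) {
    if (!all(is.finite(par))) return(1e10)
    beta <- par[seq_len(p)]
    s2b <- exp(max(min(par[p + 1L], 20), -20))
    theta <- exp(max(min(par[p + 2L], 20), -20))
    res <- inner_modes(drop(X %*% beta), s2b, theta, b_cache)
    if (!is.finite(res$loglik)) return(1e10)
    b_cache <<- res$b
    -res$loglik
  }

  start_glm <- stats::glm.fit(X, y, family = stats::poisson())
  par0 <- c(start_glm$coefficients, log(0.3), log(1))
  opt <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = ctrl$outer_maxit, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop("NB-GLMM outer optimization failed to converge (optim code ",
         opt$convergence, "): ", opt$message %||% "", call. = FALSE)
  }
  hess <- stats::optimHess(opt$par, nll)
  vcov_full <- tryCatch(solve(hess), error = function(e) {
    matrix(NA_real_, p + 2L, p + 2L)
  })
  beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  se <- sqrt(pmax(diag(vcov_full)[seq_len(p)], 0))
  names(se) <- colnames(X)
  zval <- beta / se
  final <- inner_modes(drop(X %*% beta), exp(opt$par[p + 1L]),
                       exp(opt$par[p + 2L]), b_cache)
  structure(list(
    beta = beta, se = se, statistic = zval,
    p.value = 2 * stats::pnorm(-abs(zval)),
    sigma2_b = unname(exp(opt$par[p + 1L])), theta = unname(exp(opt$par[p + 2L])),
    loglik = -opt$value, n_obs = length(y), n_groups = ng,
    vcov = vcov_full[seq_len(p), seq_len(p), drop = FALSE],
    b_modes = final$b, assign = attr(X, "assign"),
    formula = formula, group = group,
    X = X, y = y, g = g
  ), class = "nb_glmm_fit")
}

#' @export
print.nb_glmm_fit <- function(x, ...) {
  cat("Random-intercept negative-binomial mixed model (Laplace)\n")
  cat("  n_obs =", x$n_obs, ", participants =", x$n_groups,
      ", logLik =", format(x$loglik, digits = 7), "\n")
  cat("  sigma2_b =", format(x$sigma2_b, digits = 4),
      ", theta =", format(x$theta, digits = 4), "\n\nFixed effects (log scale):\n")
  print(data.frame(Estimate = x$beta, SE = x$se, z = x$statistic,
                   p = format.pval(x$p.value, digits = 3)))
  invisible(x)
}

#' Tidy a fitted NB mixed model
#'
#' @param x An `nb_glmm_fit`.
#' @param conf.level Confidence level for Wald intervals (log scale).
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect coefficient.
#' @method tidy nb_glmm_fit
#' @export
tidy.nb_glmm_fit <- function(x, conf.level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta),
    std.error = unname(x$se), statistic = unname(x$statistic),
    p.value = unname(x$p.value),
    conf.low = unname(x$beta - zq * x$se),
    conf.high = unname(x$beta + zq * x$se)
  )
}

#' One-row summary of a fitted NB mixed model
#'
#' @param x An `nb_glmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance nb_glmm_fit
#' @export
glance.nb_glmm_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_b = x$sigma2_b, theta = x$theta, logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * (length(x$beta) + 2),
    n_obs = x$n_obs, n_groups = x$n_groups
  )
}

#' @rdname autoplot.lmm_fit
#' @method autoplot nb_glmm_fit
#' @export
autoplot.nb_glmm_fit <- function(object, ...) {
  class(object) <- "lmm_fit"  # same coefficient-plot layout
  autoplot.lmm_fit(object, ...)
}
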