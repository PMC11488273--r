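#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Fits \eqn{y_{ij} = x_{ij}'\beta + b_i + \epsilon_{ij}} with
#' \eqn{b_i \sim N(0, \sigma^2_b)} and \eqn{\epsilon_{ij} \sim N(0, \sigma^2_e)}
#' by maximizing the marginal Gaussian likelihood. \eqn{\beta} and
#' \eqn{\sigma^2_e} are profiled out in closed form, leaving a one-dimensional
#' optimization of the profiled deviance over the variance ratio
#' \eqn{\lambda = \sigma^2_b / \sigma^2_e}. Because the per-participant
#' covariance is compound-symmetric, \eqn{V_i^{-1}} and \eqn{\log|V_i|} have
#' closed forms and the whole profile step costs one pass of group sums.
#'
#' Rows with a missing outcome or missing covariates are dropped (available-
#' case maximum likelihood, which is consistent when data are missing at
#' random given the modelled covariates). ML, not REML, is used throughout so
#' that likelihoods of nested mean structures are comparable. The boundary
#' \eqn{\sigma^2_b = 0} is allowed and flagged.
#'
#' @param data A data frame in long format (one row per participant x
#'   assessment).
#' @param formula Fixed-effects formula, e.g.
#'   `value ~ time_days + age_admission + los_total`.
#' @param group Name of the grouping (participant id) column.
#' @return An object of class `lmm_fit` with elements `beta`, `se`,
#'   `sigma2_b`, `sigma2_e`, `loglik`, `vcov`, `n_obs`, `n_groups`, per-term
#'   Wald statistics, and the design information needed for [partial_r2()]
#'   and parametric-bootstrap refits.
#' @seealso [tidy.lmm_fit()], [glance.lmm_fit()], [partial_r2()]
#' @export
fit_lmm <- function(data, formula, group = "participant_id") {
  stopifnot(is.data.frame(data), inherits(formula, "formula"))
  if (!group %in% names(data)) stop("grouping column '", group, "' not found",
                                    call. = FALSE)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) stop("variables not in data: ",
                                 paste(missing_vars, collapse = ", "),
                                 call. = FALSE)
  keep <- stats::complete.cases(data[vars]) & !is.na(data[[group]])
  d <- data[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, d)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  g <- factor(d[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 participants", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effects design is rank deficient after dropping incomplete rows",
         call. = FALSE)
  }
  fit <- lmm_profile_fit(X, y, g)
  fit$formula <- formula
  fit$group <- group
  fit$terms <- stats::terms(mf)
  fit$n_dropped <- sum(!keep)
  fit
}

# Core profiled-ML engine on a fixed design; reused by the parametric
# bootstrap so refits skip formula handling.
lmm_profile_fit <- function(X, y, g) {
  n <- length(y)
  p <- ncol(X)
  ni <- as.numeric(table(g))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  Sx <- rowsum(X, g)              # group sums of columns of X
  Sy <- rowsum(y, g)[, 1L]

  profile <- function(lambda) {
    ci <- lambda / (1 + lambda * ni)
    XtVX <- XtX - crossprod(Sx, ci * Sx)
    XtVy <- Xty - crossprod(Sx, ci * Sy)
    yVy <- yty - sum(ci * Sy^2)
    ch <- chol(XtVX)
    beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
    rss <- yVy - 2 * sum(beta * XtVy) + sum(beta * (XtVX %*% beta))
    rss <- max(rss, 1e-300)
    sigma2e <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2e) + sum(log1p(lambda * ni)) + n)
    list(ll = ll, beta = beta, sigma2e = sigma2e, XtVX = XtVX)
  }

  nll_u <- function(u) -profile(exp(u))$ll
  opt <- stats::optimize(nll_u, interval = c(-14, 14), tol = 1e-9)
  lambda <- exp(opt$minimum)
  # compare against the boundary sigma2_b = 0
  at0 <- profile(0)
  boundary <- FALSE
  if (at0$ll >= -opt$objective - 1e-10 || opt$minimum <= -13.5) {
    lambda <- 0
    boundary <- TRUE
  }
  sol <- profile(lambda)
  vcov <- chol2inv(chol(sol$XtVX)) * sol$sigma2e
  se <- sqrt(diag(vcov))
  beta <- drop(sol$beta)
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  zval <- beta / se
  structure(list(
    beta = beta, se = stats::setNames(se, colnames(X)),
    statistic = zval, p.value = 2 * stats::pnorm(-abs(zval)),
    sigma2_b = lambda * sol$sigma2e, sigma2_e = sol$sigma2e,
    lambda = lambda, boundary = boundary,
    loglik = sol$ll, n_obs = n, n_groups = nlevels(g),
    vcov = vcov, assign = attr(X, "assign"),
    X = X, y = y, g = g
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept linear mixed model (ML)\n")
  cat("  n_obs =", x$n_obs, ", participants =", x$n_groups,
      ", logLik =", format(x$loglik, digits = 7), "\n")
  cat("  sigma2_b =", format(x$sigma2_b, digits = 4),
      if (x$boundary) "(boundary)", ", sigma2_e =",
      format(x$sigma2_e, digits = 4), "\n\nFixed effects:\n")
  print(data.frame(Estimate = x$beta, SE = x$se, z = x$statistic,
                   p = format.pval(x$p.value, digits = 3)))
  invisible(x)
}

#' Tidy a fitted random-intercept LMM
#'
#' @param x An `lmm_fit`.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect coefficient.
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, conf.level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    p.value = unname(x$p.value),
    conf.low = unname(x$beta - zq * x$se),
    conf.high = unname(x$beta + zq * x$se)
  )
}

#' One-row model summary for a fitted LMM
#'
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with variance components, log-likelihood and
#'   sample sizes.
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_b = x$sigma2_b, sigma2_e = x$sigma2_e,
    icc = x$sigma2_b / (x$sigma2_b + x$sigma2_e),
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * (length(x$beta) + 2),
    n_obs = x$n_obs, n_groups = x$n_groups,
    boundary = x$boundary
  )
}

#' Coefficient plot for a fitted model
#'
#' Fixed-effect estimates with 95% Wald intervals, intercept omitted.
#'
#' @param object An `lmm_fit` or `nb_glmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lmm_fit
#' @export
autoplot.lmm_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "estimate (95% Wald CI)", y = NULL) +
    ggplot2::theme_minimal()
}

term_columns <- function(fit, term) {
  labels <- attr(fit$terms, "term.labels")
  if (!term %in% labels) {
    stop("term '", term, "' not in the model (terms: ",
         paste(labels, collapse = ", "), ")", call. = FALSE)
  }
  which(fit$assign == match(term, labels))
}

# A term is "within-participant" if any of its design columns varies inside
# at least one participant; otherwise it is a between-participant term.
is_within_term <- function(fit, cols) {
  for (j in cols) {
    rng <- tapply(fit$X[, j], fit$g, function(v) diff(range(v)))
    if (any(rng > 1e-12, na.rm = TRUE)) return(TRUE)
  }
  FALSE
}

#' Semi-partial R-squared for a fixed-effect term
#'
#' Effect size \eqn{R^2 = qF / (qF + \nu)} where `q` is the term's degrees of
#' freedom, `F` its Wald F statistic and \eqn{\nu} the denominator degrees of
#' freedom from the containment rule: for within-participant terms
#' \eqn{\nu = n_{obs} - \mathrm{rank}(X) - (n_{participants} - 1)}, for
#' between-participant terms \eqn{\nu = n_{participants} -
#' \mathrm{rank}(X_{between})}. The confidence interval is a parametric
#' bootstrap (simulate from the fitted model, refit, percentile interval).
#'
#' @param fit An `lmm_fit`.
#' @param term A term label from the model formula (e.g. `"time_days"`).
#' @param boot Number of parametric-bootstrap replicates (default 200; 0
#'   skips the interval).
#' @param conf.level Confidence level for the percentile interval.
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble: `term`, `partial_r2`, `conf.low`, `conf.high`,
#'   `F`, `df1`, `df2`.
#' @export
partial_r2 <- function(fit, term, boot = 200, conf.level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "lmm_fit"))
  cols <- term_columns(fit, term)
  r2_of <- function(f) {
    q <- length(cols)
    b <- f$beta[cols]
    Vt <- f$vcov[cols, cols, drop = FALSE]
    Fstat <- drop(crossprod(b, solve(Vt, b))) / q
    if (is_within_term(fit, cols)) {
      nu <- f$n_obs - ncol(f$X) - (f$n_groups - 1)
    } else {
      between <- rowsum(f$X, f$g) / as.numeric(table(f$g))
      nu <- f$n_groups - qr(between)$rank
    }
    if (nu <= 0) stop("non-positive denominator degrees of freedom", call. = FALSE)
    c(r2 = q * Fstat / (q * Fstat + nu), F = Fstat, df2 = nu)
  }
  est <- r2_of(fit)
  lo <- hi <- NA_real_
  if (boot > 0) {
    set.seed(seed)
    mu <- drop(fit$X %*% fit$beta)
    gi <- as.integer(fit$g)
    reps <- vapply(seq_len(boot), function(r) {
      b <- stats::rnorm(fit$n_groups, 0, sqrt(fit$sigma2_b))
      ystar <- mu + b[gi] + stats::rnorm(fit$n_obs, 0, sqrt(fit$sigma2_e))
      r2_of(lmm_profile_fit(fit$X, ystar, fit$g))["r2"]
    }, numeric(1))
    qs <- stats::quantile(reps, c((1 - conf.level) / 2, 1 - (1 - conf.level) / 2),
                          names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble::tibble(term = term, partial_r2 = unname(est["r2"]),
                 conf.low = lo, conf.high = hi,
                 F = unname(est["F"]), df1 = length(cols),
                 df2 = unname(est["df2"]))
}
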