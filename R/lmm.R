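#' Maximum-likelihood linear mixed model with one random intercept
#'
#' Fits `y = X beta + u[group] + e`, `u ~ N(0, tau2)`, `e ~ N(0, sigma2)`,
#' by profiling the likelihood over the variance ratio
#' `lambda = tau2 / sigma2`: for fixed `lambda` the GLS coefficients and
#' the ML residual variance are closed-form (block structure of the
#' marginal covariance), leaving a one-dimensional optimization. ML (not
#' REML) likelihoods are returned so that models with different fixed
#' effects are comparable under AICc.
#'
#' @param y Numeric response.
#' @param design Data frame or matrix of fixed-effect predictors (no
#'   intercept column; an intercept is always included). May have zero
#'   columns for an intercept-only model.
#' @param group Grouping factor for the random intercept (at least 2
#'   levels).
#' @return An object of class `colpress_lmm`: a list with `coefficients`,
#'   `vcov`, `sigma2`, `tau2`, `lambda`, `logLik`, `n`, `k` (fixed effects
#'   including intercept + 2 variance parameters), `fitted`, `ranef` and
#'   `group_levels`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(60))
#' g <- rep(letters[1:6], each = 10)
#' y <- 1 + 2 * d$x + rnorm(6, 0, 0.5)[as.integer(factor(g))] + rnorm(60)
#' fit <- fit_lmm_ml(y, d, g)
#' coef(fit)
#' @export
fit_lmm_ml <- function(y, design, group) {
  if (is.null(design) || NCOL(design) == 0) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- cbind(`(Intercept)` = 1, as.matrix(design))
  }
  if (!is.numeric(X)) abort("design must be numeric.")
  n <- length(y)
  if (nrow(X) != n) abort("design and response lengths differ.")
  g <- factor(group)
  if (nlevels(g) < 2) abort("grouping factor needs at least 2 levels.")
  p <- ncol(X)
  if (n <= p + 2) abort("too few observations for the parameter count.")
  if (qr(X)$rank < p) abort("singular fixed-effect design.")

  prof <- function(theta) lmm_profile(exp(theta), y, X, g)$neg2ll
  # profile over log(lambda), and compare with the lambda = 0 boundary
  opt <- optimize(prof, interval = c(-20, 12))
  cand <- list(c(lambda = exp(opt$minimum), neg2ll = opt$objective),
               c(lambda = 0, neg2ll = lmm_profile(0, y, X, g)$neg2ll))
  best <- cand[[which.min(vapply(cand, `[[`, 0, "neg2ll"))]]
  if (!is.finite(best[["neg2ll"]])) {
    abort("profiled likelihood did not converge; inspect the design.")
  }
  sol <- lmm_profile(best[["lambda"]], y, X, g, full = TRUE)
  structure(list(
    coefficients = sol$beta,
    vcov = sol$vcov,
    sigma2 = sol$sigma2,
    tau2 = best[["lambda"]] * sol$sigma2,
    lambda = best[["lambda"]],
    logLik = -best[["neg2ll"]] / 2,
    n = n, k = p + 2,
    fitted = sol$fitted,
    fitted_fixed = sol$fitted_fixed,
    ranef = sol$ranef,
    group_levels = levels(g)
  ), class = "colpress_lmm")
}

# closed-form GLS + ML variance for a fixed variance ratio lambda
lmm_profile <- function(lambda, y, X, g, full = FALSE) {
  n <- length(y)
  nj <- as.numeric(table(g))
  cj <- lambda / (1 + lambda * nj)          # per-group shrinkage weight
  gi <- as.integer(g)
  # weighted cross-products under W = I - sum_j c_j 1_j 1_j'
  Sx <- rowsum(X, gi)                        # group column sums
  Sy <- rowsum(y, gi)
  XtWX <- crossprod(X) - crossprod(Sx * sqrt(cj))
  XtWy <- crossprod(X, y) - crossprod(Sx * sqrt(cj), Sy * sqrt(cj))
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(neg2ll = Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- y - as.vector(X %*% beta)
  Sr <- rowsum(r, gi)
  q <- sum(r^2) - sum(cj * Sr^2)
  sigma2 <- q / n
  neg2ll <- n * (log(2 * pi * sigma2) + 1) + sum(log(1 + lambda * nj))
  if (!full) return(list(neg2ll = neg2ll))
  vc <- chol2inv(ch) * sigma2
  bet <- as.vector(beta)
  names(bet) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  shr <- (lambda * nj) / (1 + lambda * nj)
  ranef <- shr * (as.vector(Sr) / nj)
  names(ranef) <- levels(g)
  xb <- as.vector(X %*% beta)
  list(neg2ll = neg2ll, beta = bet, vcov = vc, sigma2 = sigma2,
       fitted_fixed = xb, fitted = xb + ranef[gi], ranef = ranef)
}

#' @export
coef.colpress_lmm <- function(object, ...) object$coefficients

#' @export
vcov.colpress_lmm <- function(object, ...) object$vcov

#' @export
logLik.colpress_lmm <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
print.colpress_lmm <- function(x, ...) {
  cat("<colpress_lmm> ML linear mixed model, random intercept\n")
  cat(sprintf("  n = %d, k = %d, logLik = %.3f\n", x$n, x$k, x$logLik))
  cat(sprintf("  sigma2 = %.4g, tau2 = %.4g\n", x$sigma2, x$tau2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param logLik Log-likelihood (a number or a `colpress_lmm`).
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return The AICc value.
#' @examples
#' aicc(-10, 3, 100)
#' @export
aicc <- function(logLik, k, n) {
  if (inherits(logLik, "colpress_lmm")) {
    n <- logLik$n; k <- logLik$k; logLik <- logLik$logLik
  }
  if (n <= k + 1) abort("AICc undefined: n must exceed k + 1.")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Marginal R-squared of a mixed-model fit
#'
#' The fixed-effects variance fraction
#' `var(X beta) / (var(X beta) + tau2 + sigma2)`.
#'
#' @param fit A `colpress_lmm`.
#' @return A value in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "colpress_lmm"))
  vf <- var(fit$fitted_fixed)
  vf / (vf + fit$tau2 + fit$sigma2)
}
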