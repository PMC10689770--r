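#' Logistic mixed model for establishment on trade breadth
#'
#' Fits `logit P(established) = a + b * breadth + u[group]`,
#' `u ~ N(0, tau2)`, by maximizing the marginal likelihood; the
#' per-group integral over the random intercept is evaluated by adaptive
#' Gauss-Hermite quadrature (the integrand is re-centred at each group's
#' conditional mode and scaled by its curvature). `tau` can be fixed (for
#' example at 0, which reduces the model to plain logistic regression).
#'
#' @param established 0/1 (or logical) outcome vector.
#' @param breadth Numeric predictor (for example number of trading
#'   countries).
#' @param group Grouping factor (taxonomic family).
#' @param nodes Number of quadrature nodes (default 15).
#' @param tau Optional fixed random-intercept standard deviation; `NULL`
#'   (default) estimates it.
#' @return An object of class `colpress_glmm`: `coefficients` (`intercept`,
#'   `slope`), `se`, `z`, `p_value`, `tau`, `logLik`, `n`, `n_groups`,
#'   `nodes`, `vcov`.
#' @examples
#' set.seed(2)
#' x <- rpois(300, 8)
#' g <- sample(letters[1:10], 300, TRUE)
#' y <- rbinom(300, 1, plogis(-2 + 0.1 * x))
#' fit <- fit_logistic_mixed(y, x, g)
#' fit$coefficients
#' @export
fit_logistic_mixed <- function(established, breadth, group, nodes = 15,
                               tau = NULL) {
  y <- as.integer(established)
  if (!all(y %in% c(0L, 1L))) abort("outcome must be 0/1.")
  if (length(unique(y)) < 2) {
    abort("both outcome classes must be present.")
  }
  x <- as.numeric(breadth)
  if (min(x[y == 1]) > max(x[y == 0]) || max(x[y == 1]) < min(x[y == 0])) {
    abort("outcome classes are completely separated along the predictor.")
  }
  g <- factor(group)
  gi <- as.integer(g)
  n <- length(y)
  gh <- gauss_hermite(nodes)

  start_glm <- unname(stats::glm.fit(cbind(1, x), y,
                                     family = stats::binomial())$coefficients)
  nll <- function(par) {
    beta <- par[1:2]
    tau_cur <- if (is.null(tau)) exp(par[3]) else tau
    -glmm_loglik(beta, tau_cur, y, x, gi, nlevels(g), gh)
  }
  if (is.null(tau)) {
    fit <- nlminb(c(start_glm, log(0.5)), nll,
                  control = list(iter.max = 500, eval.max = 800))
    par <- fit$par
    tau_hat <- exp(par[3])
  } else {
    fit <- nlminb(start_glm, function(p) nll(c(p, 0)),
                  control = list(iter.max = 500, eval.max = 800))
    par <- c(fit$par, NA)
    tau_hat <- tau
  }
  if (fit$convergence != 0 && fit$objective > nll(c(start_glm, 0)) + 1e-6) {
    abort("GLMM optimization failed to converge.")
  }
  if (any(abs(par[1:2]) > 30)) {
    abort("estimates diverged; the classes are likely completely separated.")
  }
  np <- if (is.null(tau)) 3L else 2L
  H <- stats::optimHess(par[seq_len(np)], function(p) {
    if (is.null(tau)) nll(p) else nll(c(p, 0))
  })
  V <- tryCatch(solve(H), error = function(e) matrix(NA, np, np))
  se <- sqrt(pmax(diag(V)[1:2], 0))
  z <- par[1:2] / se
  structure(list(
    coefficients = c(intercept = par[1], slope = par[2]),
    se = setNames(se, c("intercept", "slope")),
    z = setNames(z, c("intercept", "slope")),
    p_value = setNames(2 * pnorm(-abs(z)), c("intercept", "slope")),
    tau = tau_hat, tau_fixed = !is.null(tau),
    logLik = -fit$objective, n = n, n_groups = nlevels(g),
    nodes = nodes, vcov = V
  ), class = "colpress_glmm")
}

# marginal log-likelihood by adaptive Gauss-Hermite quadrature, vectorized
# over groups
glmm_loglik <- function(beta, tau_cur, y, x, gi, ng, gh) {
  eta <- beta[1] + beta[2] * x
  if (tau_cur < 1e-8) {
    return(sum(y * eta - log1pexp(eta)))
  }
  # per-group conditional mode via Newton on h(u) = loglik_j(u) + log phi(u)
  u <- numeric(ng)
  for (it in 1:50) {
    p <- plogis(eta + u[gi])
    g1 <- as.vector(rowsum(y - p, gi)) - u / tau_cur^2
    g2 <- -as.vector(rowsum(p * (1 - p), gi)) - 1 / tau_cur^2
    step <- g1 / g2
    u <- u - step
    if (max(abs(step)) < 1e-10) break
  }
  p <- plogis(eta + u[gi])
  h2 <- as.vector(rowsum(p * (1 - p), gi)) + 1 / tau_cur^2
  s <- 1 / sqrt(h2)
  # sum_k w_k exp(h(m + sqrt2 s x_k) + x_k^2) * sqrt2 * s
  acc <- matrix(0, ng, length(gh$x))
  for (k in seq_along(gh$x)) {
    uk <- u + sqrt(2) * s * gh$x[k]
    etak <- eta + uk[gi]
    ll_j <- as.vector(rowsum(y * etak - log1pexp(etak), gi))
    hk <- ll_j + dnorm(uk, 0, tau_cur, log = TRUE)
    acc[, k] <- hk + gh$x[k]^2 + log(gh$w[k])
  }
  m <- apply(acc, 1, max)
  sum(m + log(rowSums(exp(acc - m))) + 0.5 * log(2) + log(s))
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) via the
# Golub-Welsch eigen decomposition of the Jacobi matrix
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' @export
print.colpress_glmm <- function(x, ...) {
  cat("<colpress_glmm> logistic mixed model (adaptive Gauss-Hermite)\n")
  cat(sprintf("  n = %d in %d groups, nodes = %d, tau = %.4g\n",
              x$n, x$n_groups, x$nodes, x$tau))
  print(round(rbind(estimate = x$coefficients, se = x$se, z = x$z,
                    p = x$p_value), 4))
  invisible(x)
}
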