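# broom-style tidiers for the fitted objects

#' Tidy a mixed-model fit
#'
#' @param x A `colpress_lmm`.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.colpress_lmm <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(se),
         statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))))
}

#' @rdname tidy.colpress_lmm
#' @export
glance.colpress_lmm <- function(x, ...) {
  tibble(nobs = x$n, k = x$k, logLik = x$logLik,
         AICc = aicc(x), sigma2 = x$sigma2, tau2 = x$tau2,
         r2m = marginal_r2(x))
}

#' Tidy a logistic mixed-model fit
#'
#' @param x A `colpress_glmm`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.colpress_glmm <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(x$z),
         p.value = unname(x$p_value))
}

#' @rdname tidy.colpress_glmm
#' @export
glance.colpress_glmm <- function(x, ...) {
  tibble(nobs = x$n, n_groups = x$n_groups, tau = x$tau,
         logLik = x$logLik, nodes = x$nodes)
}

#' Tidy a model set
#'
#' @param x A `colpress_modelset`.
#' @param ... Unused.
#' @return One row per model: `model`, `n_predictors`, `logLik`, `k`,
#'   `AICc`, `delta`, `weight`, `r2m`.
#' @export
tidy.colpress_modelset <- function(x, ...) {
  tibble(model = vapply(x$predictors, function(s)
    if (length(s) == 0) "(intercept)" else paste(s, collapse = " + "), ""),
    n_predictors = x$n_predictors, logLik = x$logLik, k = x$k,
    AICc = x$aicc, delta = x$delta, weight = x$weight, r2m = x$r2m)
}

#' @rdname tidy.colpress_modelset
#' @export
glance.colpress_modelset <- function(x, ...) {
  tp <- top_models(x)
  tibble(n_models = nrow(x), n_converged = sum(x$converged),
         n_top = nrow(tp), best_aicc = min(x$aicc, na.rm = TRUE),
         r2m_min = min(tp$r2m), r2m_max = max(tp$r2m))
}
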