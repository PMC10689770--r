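#' Fit all predictor subsets of a mixed model
#'
#' Enumerates every subset of the declared predictors (including the
#' intercept-only model), fits each by [fit_lmm_ml()], and scores it with
#' [aicc()]. With the nine standard country-level predictors this is the
#' 512-model set used for multimodel inference. Subsets whose fit fails are
#' recorded, excluded from weights, and reported with a warning.
#'
#' @param y Numeric response.
#' @param design Data frame of candidate predictors (columns are the
#'   predictor set).
#' @param group Random-intercept grouping factor.
#' @return A `colpress_modelset`: a tibble with one row per subset
#'   (`model_id`, `predictors` list-column, `n_predictors`, `logLik`, `k`,
#'   `aicc`, `delta`, `weight`, `r2m`, `fit` list-column, `converged`),
#'   ordered by AICc.
#' @examples
#' set.seed(1)
#' d <- data.frame(a = rnorm(80), b = rnorm(80))
#' g <- rep(1:8, each = 10)
#' y <- 1 + d$a + rnorm(80)
#' ms <- enumerate_and_fit(y, d, g)
#' nrow(ms)  # 2^2 = 4
#' @export
enumerate_and_fit <- function(y, design, group) {
  design <- as.data.frame(design)
  preds <- names(design)
  p <- length(preds)
  subsets <- lapply(0:(2^p - 1), function(m) preds[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
  fits <- lapply(subsets, function(s) {
    tryCatch(fit_lmm_ml(y, design[, s, drop = FALSE], group),
             error = function(e) e)
  })
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (any(!ok)) {
    warn(sprintf("%d of %d subset fits failed and were excluded.",
                 sum(!ok), length(fits)))
  }
  ms <- tibble(
    model_id = seq_along(subsets),
    predictors = subsets,
    n_predictors = lengths(subsets),
    converged = ok,
    logLik = vapply(fits, function(f) if (inherits(f, "error")) NA_real_
                    else f$logLik, 0),
    k = vapply(fits, function(f) if (inherits(f, "error")) NA_real_
               else as.numeric(f$k), 0),
    fit = fits
  )
  ms$aicc <- ifelse(ms$converged,
                    vapply(seq_len(nrow(ms)), function(i)
                      if (ms$converged[i]) aicc(ms$logLik[i], ms$k[i],
                                                length(y)) else NA_real_, 0),
                    NA_real_)
  ms$r2m <- vapply(seq_len(nrow(ms)), function(i)
    if (ms$converged[i]) marginal_r2(ms$fit[[i]]) else NA_real_, 0)
  ms <- akaike_weights(ms)
  ms <- ms[order(ms$aicc), ]
  class(ms) <- c("colpress_modelset", class(ms))
  ms
}

#' Akaike weights over a model set
#'
#' `w_i` proportional to `exp(-delta_i / 2)` over the converged fits,
#' normalized to sum to one; `delta_i` is the AICc difference from the best
#' model.
#'
#' @param modelset A model-set tibble with an `aicc` column.
#' @return The model set with `delta` and `weight` columns (re)computed.
#' @export
akaike_weights <- function(modelset) {
  assert_columns(modelset, "aicc")
  d <- modelset$aicc - min(modelset$aicc, na.rm = TRUE)
  w <- exp(-d / 2)
  w[is.na(w)] <- 0
  modelset$delta <- d
  modelset$weight <- w / sum(w)
  modelset
}

#' Top models within 2 AICc units of the best
#'
#' @param modelset A `colpress_modelset`.
#' @param delta_max Inclusive threshold on the AICc difference (default 2).
#' @return The qualifying rows, sorted by ascending AICc.
#' @export
top_models <- function(modelset, delta_max = 2) {
  assert_columns(modelset, c("aicc", "delta"))
  out <- modelset[!is.na(modelset$delta) & modelset$delta <= delta_max, ]
  out[order(out$aicc), ]
}

#' Conditional model-averaged coefficients
#'
#' For each predictor, averages its coefficient over only the models that
#' contain it, with Akaike weights renormalized within that subset. The
#' unconditional standard error folds in between-model spread:
#' `SE = sum_i w_i * sqrt(var_i + (beta_i - beta_bar)^2)`. Significance is
#' the two-sided normal test at `|z| >= 1.96`.
#'
#' @param modelset A `colpress_modelset`.
#' @return A tibble of class `colpress_averaged`: `predictor`, `estimate`,
#'   `se`, `z`, `p_value`, `significant`, `n_models`, `weight_sum`.
#' @export
conditional_average <- function(modelset) {
  assert_columns(modelset, c("predictors", "weight", "fit", "converged"))
  ok <- modelset[modelset$converged, ]
  preds <- sort(unique(unlist(ok$predictors)))
  out <- bind_rows(lapply(preds, function(pr) {
    has <- vapply(ok$predictors, function(s) pr %in% s, TRUE)
    sub <- ok[has, ]
    w <- sub$weight / sum(sub$weight)
    est_i <- vapply(sub$fit, function(f) coef(f)[[pr]], 0)
    var_i <- vapply(sub$fit, function(f) vcov(f)[pr, pr], 0)
    est <- sum(w * est_i)
    se <- sum(w * sqrt(var_i + (est_i - est)^2))
    z <- est / se
    tibble(predictor = pr, estimate = est, se = se, z = z,
           p_value = 2 * pnorm(-abs(z)),
           significant = abs(z) >= 1.96,
           n_models = nrow(sub), weight_sum = sum(sub$weight))
  }))
  class(out) <- c("colpress_averaged", class(out))
  out
}

#' @export
print.colpress_modelset <- function(x, ...) {
  cat(sprintf("<colpress_modelset> %d models (%d converged)\n",
              nrow(x), sum(x$converged)))
  best <- x[which.min(x$aicc), ]
  cat(sprintf("  best: {%s}, AICc = %.2f, weight = %.3f, R2m = %.3f\n",
              paste(best$predictors[[1]], collapse = ", "),
              best$aicc, best$weight, best$r2m))
  invisible(x)
}
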