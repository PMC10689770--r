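#' Transform and standardize country-level predictors
#'
#' Prepares the nine-predictor design for the establishment-richness
#' models from a [country_richness()] summary: restricts rows to the
#' configured income classes, applies the transform conventions (natural
#' log for area, population density, GDP per capita and mean
#' precipitation; `log1p` for colonization pressure and congeneric
#' richness; `log1p` for the establishment-richness response), then
#' z-scores every continuous predictor. Binary insularity stays 0/1.
#'
#' @param summary A [country_richness()] table filtered to one class (or
#'   any table with the needed columns).
#' @param income_classes Income classes to keep (default upper-middle and
#'   high).
#' @param response Column to use as the response (default
#'   `establishment_richness`); transformed with `log1p`, not
#'   standardized.
#' @param standardize One of `"zscore"` (default) or `"none"`.
#' @return A tibble with `country`, `realm`, `y` (transformed response)
#'   and the nine standardized predictor columns.
#' @export
transform_predictors <- function(summary,
                                 income_classes = c("upper-middle", "high"),
                                 response = "establishment_richness",
                                 standardize = c("zscore", "none")) {
  standardize <- match.arg(standardize)
  assert_columns(summary, c("country", "realm", "income_class", "area_km2",
                            "pop_density", "gdp_pc", "alien_richness",
                            "insularity", "mean_temperature",
                            "mean_precipitation", "congeneric_richness",
                            "sampling_effort", response))
  df <- summary[summary$income_class %in% income_classes, ]
  if (nrow(df) == 0) abort("no rows left after the income-class filter.")
  for (col in c("area_km2", "pop_density", "gdp_pc", "mean_precipitation")) {
    bad <- which(df[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("log transform undefined: `%s` non-positive for %s",
                    col, paste(df$country[head(bad, 5)], collapse = ", ")))
    }
  }
  out <- tibble(
    country = df$country,
    realm = df$realm,
    y = log1p(df[[response]]),
    area = log(df$area_km2),
    pop_density = log(df$pop_density),
    gdp_pc = log(df$gdp_pc),
    colonization_pressure = log1p(df$alien_richness),
    insularity = as.numeric(df$insularity),
    mean_temperature = df$mean_temperature,
    mean_precipitation = log(df$mean_precipitation),
    congeneric_richness = log1p(df$congeneric_richness),
    sampling_effort = df$sampling_effort
  )
  if (standardize == "zscore") {
    cont <- setdiff(predictor_names(), "insularity")
    for (col in cont) {
      s <- sd(out[[col]])
      out[[col]] <- if (s > 0) (out[[col]] - mean(out[[col]])) / s
      else out[[col]] - mean(out[[col]])
    }
  }
  out
}

#' Names of the nine standard country-level predictors
#'
#' @return Character vector in design order.
#' @export
predictor_names <- function() {
  c("area", "pop_density", "gdp_pc", "colonization_pressure", "insularity",
    "mean_temperature", "mean_precipitation", "congeneric_richness",
    "sampling_effort")
}

#' All-subsets establishment-richness inference for one class
#'
#' Convenience wrapper: transforms predictors, enumerates and fits all
#' 2^9 models with a realm random intercept, and returns the model set
#' plus conditionally averaged coefficients and top models.
#'
#' @param summary A [country_richness()] table restricted to one class.
#' @param income_classes Passed to [transform_predictors()].
#' @return A list: `modelset`, `averaged`, `top`, `design`.
#' @export
establishment_inference <- function(summary,
                                    income_classes = c("upper-middle",
                                                       "high")) {
  design <- transform_predictors(summary, income_classes = income_classes)
  ms <- enumerate_and_fit(design$y, design[, predictor_names()],
                          design$realm)
  list(modelset = ms,
       averaged = conditional_average(ms),
       top = top_models(ms),
       design = design)
}

#' Univariate socio-economic correlates of alien trade richness
#'
#' One linear mixed model per socio-economic factor: the response is
#' `log1p(alien richness)`, the factor is log transformed, and realm is
#' the random intercept. Reports the slope, its p value, and the marginal
#' R-squared as the variation accounted for.
#'
#' @param summary A [country_richness()] table restricted to one class.
#' @param factors Named columns to test (default human population, GDP per
#'   capita and commercial trade value).
#' @param income_classes Income-class filter applied before fitting.
#' @return A tibble: `factor`, `slope`, `se`, `z`, `p_value`, `r2m`, `n`.
#' @export
univariate_socioeconomic <- function(summary,
                                     factors = c("population", "gdp_pc",
                                                 "trade_value"),
                                     income_classes = c("upper-middle",
                                                        "high")) {
  assert_columns(summary, c("alien_richness", "realm", "income_class",
                            factors))
  df <- summary[summary$income_class %in% income_classes, ]
  if (nrow(df) == 0) abort("no rows left after the income-class filter.")
  y <- log1p(df$alien_richness)
  bind_rows(lapply(factors, function(f) {
    xv <- df[[f]]
    if (any(xv <= 0)) {
      abort(sprintf("log transform undefined for factor `%s`.", f))
    }
    d <- data.frame(x = log(xv))
    names(d) <- f
    fit <- fit_lmm_ml(y, d, df$realm)
    tibble(factor = f,
           slope = coef(fit)[[f]],
           se = sqrt(vcov(fit)[f, f]),
           z = coef(fit)[[f]] / sqrt(vcov(fit)[f, f]),
           p_value = 2 * pnorm(-abs(coef(fit)[[f]] /
                                      sqrt(vcov(fit)[f, f]))),
           r2m = marginal_r2(fit),
           n = fit$n)
  }))
}

#' Paired comparison of per-country alien and native richness
#'
#' Two-sided paired t test on the per-country differences. Zero-variance
#' differences are reported as undefined, except the all-zero case where
#' `t = 0, p = 1` by convention.
#'
#' @param alien,native Equal-length numeric vectors (per-country counts).
#' @return A tibble: `mean_diff`, `statistic`, `df`, `p_value`, `defined`.
#' @export
paired_compare <- function(alien, native) {
  if (length(alien) != length(native)) abort("vectors must be paired.")
  if (length(alien) < 2) abort("need at least 2 pairs.")
  d <- alien - native
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(mean_diff = 0, statistic = 0,
                    df = length(d) - 1, p_value = 1, defined = TRUE))
    }
    return(tibble(mean_diff = mean(d), statistic = NA_real_,
                  df = length(d) - 1, p_value = NA_real_, defined = FALSE))
  }
  tt <- t.test(alien, native, paired = TRUE)
  tibble(mean_diff = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value, defined = TRUE)
}

#' Cross-taxa correlation of per-country alien richness
#'
#' Pearson correlations of alien trade richness across countries between
#' the four vertebrate classes.
#'
#' @param summary A [country_richness()] table (all classes).
#' @param value Column to correlate (default `alien_richness`).
#' @param log_scale Correlate on the `log1p` scale if `TRUE` (default
#'   `FALSE`).
#' @return A symmetric correlation matrix with unit diagonal; entries for
#'   zero-variance classes are `NA` (with a warning).
#' @export
cross_taxa_correlation <- function(summary, value = "alien_richness",
                                   log_scale = FALSE) {
  assert_columns(summary, c("country", "class", value))
  df <- summary[summary$class != "total", ]
  wide <- tidyr::pivot_wider(df[, c("country", "class", value)],
                             names_from = "class",
                             values_from = dplyr::all_of(value))
  if (nrow(wide) < 3) abort("need at least 3 countries.")
  m <- as.matrix(wide[, -1])
  if (log_scale) m <- log1p(m)
  zv <- apply(m, 2, sd) == 0
  if (any(zv)) {
    warn(sprintf("zero-variance class(es): %s; correlations undefined.",
                 paste(colnames(m)[zv], collapse = ", ")))
  }
  suppressWarnings(r <- cor(m))
  diag(r) <- 1
  r
}
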