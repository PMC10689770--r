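test_that("with no group variance the ML fit collapses to OLS", {
  set.seed(101)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  g <- rep(letters[1:6], each = 20)
  y <- 2 + 0.8 * d$x1 - 0.5 * d$x2 + rnorm(n, 0, 0.4)
  fit <- fit_lmm_ml(y, d, g)
  ols <- coef(lm(y ~ x1 + x2, data = d))
  expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-6)
})

test_that("intercept-only fit with one observation per group profiles to the mean", {
  fit <- fit_lmm_ml(c(1, 2, 3, 4, 5), NULL, factor(1:5))
  expect_equal(unname(coef(fit)), 3, tolerance = 1e-8)
})

test_that("profiled likelihood matches a brute-force lambda grid", {
  set.seed(5)
  g <- rep(1:6, each = 8)
  d <- data.frame(x = rnorm(48))
  y <- 1 + d$x + rnorm(6, 0, 1.2)[g] + rnorm(48, 0, 0.8)
  fit <- fit_lmm_ml(y, d, g)
  X <- cbind(1, d$x)
  # coarse linear grid: the fit must dominate every grid point
  grid <- seq(0, 1e4, length.out = 2000)
  ll <- vapply(grid, oracle_lmm_loglik, 0, y = y, des = X, g = g)
  expect_gte(fit$logLik, max(ll) - 1e-8)
  # fine log-spaced grid around the optimum pins the maximum to 1e-4
  fine <- c(0, exp(seq(log(1e-4), log(1e4), length.out = 2000)))
  llf <- vapply(fine, oracle_lmm_loglik, 0, y = y, des = X, g = g)
  expect_equal(fit$logLik, max(llf), tolerance = 1e-4)
})

test_that("fit agrees with lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  set.seed(11)
  n <- 150
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  g <- sample(letters[1:8], n, TRUE)
  y <- 1 + 0.4 * d$a + rnorm(8, 0, 0.9)[as.integer(factor(g))] + rnorm(n)
  fit <- fit_lmm_ml(y, d, g)
  dd <- cbind(d, y = y, g = g)
  lf <- lme4::lmer(y ~ a + b + (1 | g), data = dd, REML = FALSE)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-5)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(lf)),
               tolerance = 1e-5)
  expect_equal(fit$sigma2, stats::sigma(lf)^2, tolerance = 1e-4)
})

test_that("degenerate designs are rejected with informative errors", {
  y <- rnorm(30)
  g <- rep(1:3, each = 10)
  expect_error(fit_lmm_ml(y, data.frame(x = rep(1, 30)), g), "singular")
  expect_error(fit_lmm_ml(y, NULL, rep(1, 30)), "2 levels")
  expect_error(fit_lmm_ml(rnorm(4), data.frame(x = rnorm(4)), c(1, 1, 2, 2)),
               "too few")
})

test_that("aicc follows the closed form and its domain limits", {
  expect_equal(aicc(-10, 3, 100), 26.25)
  expect_equal(aicc(-10, 3, 1e9), -2 * (-10) + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(-10, 9, 10), "undefined")
})

test_that("marginal R2 tracks a known variance partition", {
  # var(Xb) = 2, tau2 = 1, sigma2 = 1 -> R2m = 0.5
  set.seed(202)
  n <- 2000
  x <- rnorm(n)
  g <- sample(1:25, n, TRUE)
  y <- sqrt(2) * x + rnorm(25, 0, 1)[g] + rnorm(n, 0, 1)
  fit <- fit_lmm_ml(y, data.frame(x = x), g)
  expect_lt(abs(marginal_r2(fit) - 0.5), 0.05)
  # noiseless linear data -> R2m near 1
  y2 <- 3 * x
  fit2 <- fit_lmm_ml(y2, data.frame(x = x), g)
  expect_gt(marginal_r2(fit2), 0.999)
})

test_that("tidiers return broom-shaped frames", {
  set.seed(1)
  d <- data.frame(x = rnorm(60))
  g <- rep(1:6, each = 10)
  fit <- fit_lmm_ml(1 + d$x + rnorm(60), d, g)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value"))
  gl <- glance(fit)
  expect_equal(gl$AICc, aicc(fit))
  expect_equal(gl$nobs, 60)
})
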