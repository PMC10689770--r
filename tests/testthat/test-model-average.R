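make_ms <- function(p = 2, n = 80, seed = 3) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n,
                            dimnames = list(NULL, paste0("x", seq_len(p)))))
  g <- rep(1:8, length.out = n)
  y <- 1 + d$x1 + rnorm(8, 0, 0.5)[g] + rnorm(n, 0, 0.7)
  list(ms = enumerate_and_fit(y, d, g), d = d, y = y, g = g)
}

test_that("enumeration covers every subset including intercept-only", {
  out <- make_ms(p = 2)
  expect_equal(nrow(out$ms), 4)
  expect_true(any(out$ms$n_predictors == 0))
  single <- enumerate_and_fit(out$y, out$d[, 0, drop = FALSE], out$g)
  expect_equal(nrow(single), 1)
  p3 <- make_ms(p = 3)
  expect_equal(nrow(p3$ms), 8)
})

test_that("model-set AICc is consistent with an independent recomputation", {
  out <- make_ms(p = 2)
  full <- out$ms[out$ms$n_predictors == 2, ]
  expect_equal(full$aicc,
               aicc(full$logLik, full$k, length(out$y)))
  expect_equal(min(out$ms$delta), 0)
})

test_that("akaike weights follow exp(-delta/2) normalization", {
  ms <- tibble::tibble(aicc = c(100, 102), converged = TRUE)
  ms <- akaike_weights(ms)
  expect_equal(ms$weight, c(0.7311, 0.2689), tolerance = 1e-4)
  ms2 <- akaike_weights(tibble::tibble(aicc = rep(50, 4), converged = TRUE))
  expect_equal(ms2$weight, rep(0.25, 4))
  out <- make_ms(p = 3)
  expect_equal(sum(out$ms$weight), 1, tolerance = 1e-12)
})

test_that("top models use the inclusive 2-unit threshold", {
  ms <- tibble::tibble(aicc = c(10, 11.9, 12.1, 12.0),
                       delta = c(0, 1.9, 2.1, 2.0), converged = TRUE)
  tp <- top_models(ms)
  expect_equal(tp$delta, c(0, 1.9, 2.0))
  one <- top_models(tibble::tibble(aicc = 5, delta = 0, converged = TRUE))
  expect_equal(nrow(one), 1)
})

test_that("conditional averaging matches hand-computed sums on a fixture", {
  fake_fit <- function(b, v) {
    structure(list(coefficients = c(`(Intercept)` = 0, xx = b),
                   vcov = matrix(c(1, 0, 0, v), 2,
                                 dimnames = list(c("(Intercept)", "xx"),
                                                 c("(Intercept)", "xx")))),
              class = "colpress_lmm")
  }
  ms <- tibble::tibble(
    predictors = list("xx", "xx", character(0)),
    weight = c(0.3, 0.2, 0.5),
    converged = TRUE,
    fit = list(fake_fit(1, 0.04), fake_fit(3, 0.09), NULL))
  avg <- conditional_average(ms)
  # renormalized weights 0.6 / 0.4; estimate = 0.6*1 + 0.4*3 = 1.8
  expect_equal(avg$estimate, 1.8)
  se_hand <- 0.6 * sqrt(0.04 + (1 - 1.8)^2) + 0.4 * sqrt(0.09 + (3 - 1.8)^2)
  expect_equal(avg$se, se_hand)
  expect_equal(avg$z, 1.8 / se_hand)
  expect_equal(avg$significant, abs(avg$z) >= 1.96)
  # single-model predictor: estimate equals that model's, SE at least its SE
  ms1 <- ms[c(1, 3), ]
  ms1$weight <- c(0.4, 0.6)
  avg1 <- conditional_average(ms1)
  expect_equal(avg1$estimate, 1)
  expect_gte(avg1$se, sqrt(0.04))
})

test_that("averaging degenerates to the full model when it has all the weight", {
  set.seed(8)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  g <- rep(1:10, each = 30)
  # both predictors strongly present: the full model dominates
  y <- 1 + 3 * d$x1 + 3 * d$x2 + rnorm(10, 0, 0.3)[g] + rnorm(n, 0, 0.5)
  ms <- enumerate_and_fit(y, d, g)
  full_w <- ms$weight[ms$n_predictors == 2]
  expect_gt(full_w, 0.999)
  avg <- conditional_average(ms)
  full_fit <- ms$fit[[which(ms$n_predictors == 2)]]
  expect_equal(avg$estimate[avg$predictor == "x1"],
               unname(coef(full_fit)["x1"]), tolerance = 1e-3)
})
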