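test_that("predictor transforms follow the stated conventions", {
  cs <- country_richness(tiny$classified, tiny$species, tiny$world)
  cs <- cs[cs$class == "total", ]
  des <- transform_predictors(cs, income_classes = unique(cs$income_class))
  expect_equal(des$y, log1p(cs$establishment_richness))
  for (col in setdiff(predictor_names(), "insularity")) {
    expect_equal(mean(des[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(des[[col]]), 1, tolerance = 1e-12)
  }
  expect_true(all(des$insularity %in% c(0, 1)))
  # log of a non-positive covariate names the offending rows
  bad <- cs
  bad$area_km2[3] <- -1
  expect_error(transform_predictors(bad,
                                    income_classes = unique(cs$income_class)),
               "area_km2")
})

test_that("income-class filter restricts the analysis rows", {
  cs <- country_richness(tiny$classified, tiny$species, tiny$world)
  cs <- cs[cs$class == "total", ]
  des <- transform_predictors(cs)
  kept <- cs$income_class %in% c("upper-middle", "high")
  expect_equal(nrow(des), sum(kept))
  expect_error(transform_predictors(cs, income_classes = "no-such"),
               "income")
})

test_that("univariate socio-economic fits recover exact and null cases", {
  set.seed(55)
  n <- 120
  w <- tibble::tibble(
    alien_richness = 0, realm = rep(letters[1:6], each = 20),
    income_class = "high",
    population = rlnorm(n, 15, 1), gdp_pc = rlnorm(n, 9, 1),
    trade_value = rlnorm(n, 20, 1))
  # noiseless y = 2 log(population): R2m ~ 1 and a positive slope
  w$alien_richness <- expm1(2 * log(w$population) - 25)
  uni <- univariate_socioeconomic(w, factors = "population")
  expect_gt(uni$r2m, 0.999)
  expect_gt(uni$slope, 0)
  expect_lt(uni$p_value, 1e-10)
})

test_that("permuted predictors are null in most replicates", {
  set.seed(66)
  n <- 90
  hits <- vapply(1:50, function(r) {
    w <- tibble::tibble(
      realm = rep(letters[1:6], each = 15), income_class = "high",
      population = rlnorm(n, 15, 1))
    w$alien_richness <- rpois(n, 20)  # independent of the predictor
    w$population <- sample(w$population)
    univariate_socioeconomic(w, factors = "population")$p_value > 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("generator's positive trade-value effect is recovered", {
  cfg <- tiny_cfg(seed = 12, scale = 0.2, n_countries = 60)
  fx <- build_fixture(cfg)
  cs <- country_richness(fx$classified, fx$species, fx$world)
  uni <- univariate_socioeconomic(cs[cs$class == "total", ],
                                  factors = "trade_value")
  expect_gt(uni$slope, 0)
  expect_lt(uni$p_value, 0.05)
})

test_that("paired comparison handles regular and degenerate inputs", {
  x <- c(4, 6, 8, 5, 9)
  y <- c(3, 5, 9, 2, 6)
  out <- paired_compare(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out$statistic, t_hand)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), length(d) - 1))
  same <- paired_compare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  const <- paired_compare(x + 1, x)
  expect_false(const$defined)
})

test_that("cross-taxa correlations honor exact and degenerate cases", {
  cs <- tibble::tibble(
    country = rep(sprintf("C%d", 1:5), each = 4),
    class = rep(c("mammal", "bird", "reptile", "amphibian"), 5),
    alien_richness = 0)
  base <- c(3, 9, 1, 6, 8)
  cs$alien_richness <- rep(base, each = 4)
  r <- cross_taxa_correlation(cs)
  expect_true(all(abs(r - 1) < 1e-12))
  # a column and its negation correlate at -1
  cs2 <- cs
  cs2$alien_richness[cs2$class == "bird"] <- -base
  r2 <- cross_taxa_correlation(cs2)
  expect_equal(r2["mammal", "bird"], -1)
  # zero-variance class flagged
  cs3 <- cs
  cs3$alien_richness[cs3$class == "reptile"] <- 7
  expect_warning(r3 <- cross_taxa_correlation(cs3), "zero-variance")
  expect_true(is.na(r3["mammal", "reptile"]))
})

test_that("shared importing-power factor induces positive cross-taxa correlation", {
  cs <- country_richness(tiny$classified, tiny$species, tiny$world)
  r <- cross_taxa_correlation(cs)
  off <- r[upper.tri(r)]
  expect_true(all(off > 0))
})
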