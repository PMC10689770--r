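test_that("established matching is an intersection with share reporting", {
  m <- match_established(c("a", "b"), c("b", "c"))
  expect_equal(m$established_by_trade, "b")
  expect_equal(match_established(c("a"), c("b"))$n_matched, 0)
  # printed totals: 814 of 1041 established species were traded
  m2 <- match_established(sprintf("sp%04d", 1:1041), sprintf("sp%04d", 1:814))
  expect_equal(m2$share_of_established, 78.2)
  # symmetric and idempotent on the matched set
  m3 <- match_established(m$established_by_trade, c("b", "c"))
  expect_equal(m3$established_by_trade, "b")
})

test_that("trade breadth counts distinct countries and sums areas", {
  w <- tibble::tibble(country = c("A", "B"), area_km2 = c(10, 20))
  cl <- tibble::tibble(accepted_name = "s1", country = c("A", "B", "B"))
  br <- trade_breadth(cl, w, tibble::tibble(accepted_name = "s1",
                                            class = "bird"))
  expect_equal(br$n_trade_countries, 2L)
  expect_equal(br$trade_area_km2, 30)
  # missing area warns and contributes zero
  cl2 <- tibble::tibble(accepted_name = "s1", country = c("A", "Z"))
  expect_warning(br2 <- trade_breadth(cl2, w,
                                      tibble::tibble(accepted_name = "s1",
                                                     class = "bird")),
                 "no area")
  expect_equal(br2$trade_area_km2, 10)
})

test_that("breadth summary reproduces printed ratios and flags degeneracy", {
  br <- tibble::tibble(
    accepted_name = sprintf("s%02d", 1:8),
    class = "mammal",
    established = rep(c(1, 0), each = 4),
    trade_area_km2 = 1)
  # group means fixed at the printed values 18.3 vs 15.5
  br$n_trade_countries <- c(18.3, 18.3, 18.3, 18.3, 15.5, 15.5, 15.5, 15.5)
  bs <- breadth_summary(br)
  expect_equal(bs$ratio, 1.18)
  br$n_trade_countries <- rep(9.5, 8)
  br$n_trade_countries[br$established == 0] <- 7.1
  expect_equal(breadth_summary(br)$ratio, 1.34)
  # identical groups give ratio 1
  br$n_trade_countries <- 5
  expect_equal(breadth_summary(br)$ratio, 1)
  # single-species group flagged
  one <- br[c(1, 5), ]
  expect_true(breadth_summary(one)$degenerate)
})

test_that("positive establishment slope raises established-group breadth", {
  cfg <- tiny_cfg(seed = 77, scale = 0.15)
  fx <- build_fixture(cfg)
  est <- simulate_establishment(fx$classified, fx$species, fx$world, cfg)
  alien <- est$species_flags$accepted_name[est$species_flags$alien_anywhere]
  estd <- est$species_flags$accepted_name[est$species_flags$established &
                                            est$species_flags$alien_anywhere]
  br <- trade_breadth(fx$classified[fx$classified$accepted_name %in% alien, ],
                      fx$world, fx$species, established = estd)
  grp <- split(br$n_trade_countries, br$established)
  expect_gt(mean(grp[["1"]]), mean(grp[["0"]]))
})
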