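range_row <- function(extant = character(0), possibly = character(0),
                      extinct = character(0), pex = character(0),
                      introduced = character(0), name = "Testus aa",
                      class = "reptile") {
  tibble::tibble(accepted_name = name, class = class,
                 native_extant = list(extant),
                 native_possibly_extant = list(possibly),
                 extinct_range = list(extinct),
                 possibly_extinct = list(pex),
                 introduced = list(introduced))
}

test_that("native range unions presence classes and excludes introduced", {
  sp <- range_row(extant = "FR", extinct = "ES", introduced = "US")
  expect_setequal(native_range(sp)$native_countries[[1]], c("FR", "ES"))
  expect_length(native_range(range_row())$native_countries[[1]], 0)
  expect_length(native_range(range_row(introduced = c("US", "MX")))$
                  native_countries[[1]], 0)
})

test_that("record classification follows set membership", {
  sp <- range_row(extant = c("FR", "ES"))
  rec <- tibble::tibble(accepted_name = "Testus aa",
                        country = c("DE", "FR", "ES"))
  out <- classify_records(rec, sp)
  expect_equal(out$label, c("alien", "native", "native"))
  # unknown range is labeled, not dropped
  out2 <- classify_records(tibble::tibble(accepted_name = "Testus aa",
                                          country = "DE"), range_row())
  expect_equal(out2$label, "unknown-range")
  expect_error(classify_records(tibble::tibble(accepted_name = "Nope x",
                                               country = "DE"), sp),
               "absent")
})

test_that("species alien status flags follow the record pattern", {
  cl <- tibble::tibble(
    accepted_name = c("s1", "s2", "s2", "s3"),
    country = c("DE", "DE", "FR", "FR"),
    label = c("alien", "alien", "native", "native"))
  st <- species_alien_status(cl)
  expect_equal(st$alien_anywhere, c(TRUE, TRUE, FALSE))
  expect_equal(st$both_alien_and_native, c(FALSE, TRUE, FALSE))
  expect_equal(st$native_only, c(FALSE, FALSE, TRUE))
})

test_that("classification matches the generator's planted labels exactly", {
  led <- trade_ledger(tiny$raw)
  chk <- dplyr::inner_join(tiny$classified, led$truth_pairs,
                           by = c("accepted_name", "country"),
                           suffix = c("", "_truth"))
  expect_gt(nrow(chk), 0)
  expect_equal(sum(chk$label != chk$label_truth), 0)
})

test_that("country richness matches an independent group-by recount", {
  cl <- tiny$classified
  est <- tibble::tibble(accepted_name = cl$accepted_name[1:5],
                        country = cl$country[1:5])
  cs <- country_richness(cl, tiny$species, tiny$world, est)
  # independent recount via aggregate on a sampled subset of countries
  for (cc in head(unique(cl$country), 10)) {
    sub <- cl[cl$country == cc & cl$label == "alien", ]
    expect_equal(cs$alien_richness[cs$country == cc & cs$class == "total"],
                 length(unique(sub$accepted_name)))
  }
  # one alien record -> richness 1 there, 0 native
  single <- classify_records(
    tibble::tibble(accepted_name = "Testus aa", country = "C1"),
    range_row(extant = "C2"))
  w1 <- tiny$world[1:2, ]
  w1$country <- c("C1", "C2")
  cs1 <- country_richness(single, range_row(extant = "C2"), w1)
  expect_equal(cs1$alien_richness[cs1$country == "C1" &
                                    cs1$class == "total"], 1L)
  expect_equal(cs1$native_richness[cs1$country == "C1" &
                                     cs1$class == "total"], 0L)
})

test_that("duplicate sources never inflate colonization pressure", {
  sp <- range_row(extant = "C2")
  rec <- tibble::tibble(accepted_name = "Testus aa",
                        country = c("C1", "C1"),
                        source = c("CITES", "OTAPS"))
  out <- classify_records(rec, sp)
  w1 <- tiny$world[1:2, ]
  w1$country <- c("C1", "C2")
  cs <- country_richness(out, sp, w1)
  expect_equal(cs$alien_richness[cs$country == "C1" &
                                   cs$class == "total"], 1L)
})

test_that("alien plus native richness equals distinct species when all ranges known", {
  cl <- tiny$classified
  expect_equal(sum(cl$label == "unknown-range"), 0)
  cs <- country_richness(cl, tiny$species, tiny$world)
  per_country <- cl %>%
    dplyr::group_by(country) %>%
    dplyr::summarise(n = dplyr::n_distinct(accepted_name))
  tot <- cs[cs$class == "total", ]
  merged <- dplyr::left_join(per_country, tot, by = "country")
  expect_equal(merged$alien_richness + merged$native_richness, merged$n)
})

test_that("venn regions partition the union and match printed-count shares", {
  vc <- venn_counts(list(A = c("1", "2"), B = "2", C = character(0),
                         D = character(0)))
  expect_equal(vc$unique_n, 1L)
  expect_equal(vc$regions$n[vc$regions$membership == "A&B"], 1L)
  expect_equal(vc$union_size, 2L)
  expect_equal(sum(vc$regions$n), vc$union_size)

  src_sets <- split(tiny$classified$accepted_name, tiny$classified$source)
  vt <- venn_counts(src_sets[c("CITES", "LEMIS", "ISIS", "OTAPS")])
  expect_equal(sum(vt$regions$n), vt$union_size)
  expect_error(venn_counts(src_sets[1:3]), "four")
})

test_that("share metrics reproduce printed-precision rounding", {
  sm <- share_metrics(n_traded = 7780, n_extant = 34285, n_alien = 6664,
                      n_established_traded = 814,
                      n_established_total = 1041,
                      n_native_only = 1116, n_both = 4392)
  val <- setNames(sm$value, sm$metric)
  expect_equal(val[["alien_of_traded"]], 85.7)
  expect_equal(val[["established_of_alien"]], 12.2)
  expect_equal(val[["traded_of_established"]], 78.2)
  expect_equal(val[["traded_of_extant"]], 22.7)
  expect_equal(val[["native_only_of_traded"]], 14.3)
  expect_equal(val[["both_of_alien"]], 65.9)
  zero <- share_metrics(n_traded = 10, n_alien = 0)
  expect_equal(zero$value[zero$metric == "alien_of_traded"], 0)
  undef <- share_metrics(n_traded = 0, n_alien = 0)
  expect_false(undef$defined[undef$metric == "alien_of_traded"])
})
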