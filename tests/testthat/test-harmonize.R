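test_that("key index orders by length then lexicographically", {
  idx <- build_key_index(data.frame(
    key_string = c("boa constrictor", "boa"),
    accepted_name = c("Boa constrictor", "Boa constrictor")))
  expect_equal(idx$key_string, c("boa", "boa constrictor"))
  idx2 <- build_key_index(data.frame(key_string = c("Ab", "aa"),
                                     accepted_name = c("s1", "s1")))
  expect_equal(idx2$key_string, c("aa", "ab"))
})

test_that("ambiguous keys raise an error listing the collision", {
  expect_error(build_key_index(data.frame(
    key_string = c("x", "x"), accepted_name = c("sp1", "sp2"))),
    "ambiguous")
  # the same mapping twice is not ambiguous
  expect_silent(build_key_index(data.frame(
    key_string = c("x", "X"), accepted_name = c("sp1", "sp1"))))
  expect_error(build_key_index(data.frame(key_string = character(0),
                                          accepted_name = character(0))),
               "empty")
})

test_that("extract_name returns the longest key, case-insensitively", {
  idx <- build_key_index(data.frame(
    key_string = c("python", "burmese python", "xenopus laevis"),
    accepted_name = c("Python bivittatus", "Python bivittatus",
                      "Xenopus laevis")))
  expect_equal(extract_name("Burmese python hatchling, ships nationwide",
                            idx), "burmese python")
  expect_equal(extract_name("XENOPUS LAEVIS adults", idx),
               "xenopus laevis")
  expect_true(is.na(extract_name("aquarium gravel 5kg", idx)))
})

test_that("extract_name agrees with the brute-force oracle", {
  set.seed(7)
  words <- c("boa", "gecko", "tree", "green", "blue", "giant", "imperial",
             "python", "frog", "monitor", "anole", "tortoise")
  for (rep in 1:20) {
    keys <- unique(vapply(1:15, function(i)
      paste(sample(words, sample(1:3, 1)), collapse = " "), ""))
    idx <- build_key_index(data.frame(key_string = keys,
                                      accepted_name = "sp"))
    texts <- vapply(1:25, function(i)
      paste(sample(c(words, c("for", "sale", "cheap", "adult", "12cm")),
                   sample(2:8, 1), replace = TRUE), collapse = " "), "")
    expect_equal(extract_name(texts, idx), oracle_extract(texts, keys))
  }
})

test_that("word-boundary mode suppresses inner-substring matches", {
  idx <- build_key_index(data.frame(key_string = "anole",
                                    accepted_name = "Anolis sp"))
  expect_equal(extract_name("rare anoles here", idx), "anole")
  expect_true(is.na(extract_name("rare anoles here", idx,
                                 word_boundary = TRUE)))
  expect_equal(extract_name("one anole here", idx, word_boundary = TRUE),
               "anole")
})

test_that("resolve_accepted looks up synonyms, identities and unknowns", {
  keys <- data.frame(
    key_string = c("python molurus bivittatus", "python bivittatus"),
    accepted_name = c("Python bivittatus", "Python bivittatus"))
  expect_equal(resolve_accepted("Python molurus bivittatus", keys),
               "Python bivittatus")
  expect_equal(resolve_accepted("Python bivittatus", keys),
               "Python bivittatus")
  expect_true(is.na(resolve_accepted("unknown thing", keys)))
})

test_that("cleaning applies each rule once on a planted fixture", {
  fixture <- tibble::tibble(
    source = c("CITES", "CITES", "CITES", "CITES", "LEMIS", "ISIS"),
    sci_name = c("Aus bus", "Aus bus", NA, "Aus sp.", "Aus bus", "Aus bus"),
    listing_text = NA_character_,
    importer = c("C1", "C1", "C2", "C2", "C3", NA),
    exporter = c("C2", "C2", "C3", "C3", "C3", NA),
    country = c("C1", "C1", "C2", "C2", "C3", "C4"),
    year = c(2000L, 2000L, 2001L, 2002L, 2003L, 2011L),
    term = c("live", "live", "live", "live", "live", NA))
  # planted: 1 duplicate (rows 1/2), 1 missing name, 1 genus-only,
  # 1 same importer/exporter
  out <- clean_trade_records(fixture)
  expect_equal(nrow(out), 2)
  report <- attr(out, "report")
  expect_equal(sum(report$removed), 4)
  expect_equal(report$removed[report$rule == "duplicated_line"], 1L)
  expect_equal(report$removed[report$rule == "missing_name"], 1L)
  expect_equal(report$removed[report$rule == "unidentified_or_hybrid"], 1L)
  expect_equal(report$removed[report$rule == "same_importer_exporter"], 1L)
})

test_that("cleaning is idempotent and reconciles counts", {
  cleaned <- clean_trade_records(tiny$raw)
  report <- attr(cleaned, "report")
  expect_equal(sum(report$removed), nrow(tiny$raw) - nrow(cleaned))
  again <- clean_trade_records(cleaned)
  expect_equal(nrow(again), nrow(cleaned))
  expect_equal(sum(attr(again, "report")$removed), 0)
})

test_that("unknown source labels are rejected", {
  bad <- tiny$raw[1:3, ]
  bad$source <- "EBAY"
  expect_error(clean_trade_records(bad), "unknown source")
})

test_that("ISIS threatened exclusion only touches ISIS rows", {
  sp <- tibble::tibble(accepted_name = c("En sp", "Lc sp"),
                       iucn_category = c("EN", "LC"))
  rec <- tibble::tibble(
    source = c("ISIS", "CITES", "ISIS"),
    accepted_name = c("En sp", "En sp", "Lc sp"),
    country = "C1")
  out <- exclude_isis_threatened(rec, sp)
  expect_equal(attr(out, "n_excluded"), 1L)
  expect_equal(nrow(out), 2)
  # the threatened species survives through its CITES row
  expect_true("En sp" %in% out$accepted_name)
  # an EN species with only ISIS rows disappears entirely
  only_isis <- rec[rec$source == "ISIS" & rec$accepted_name == "En sp", ]
  expect_false("En sp" %in%
                 exclude_isis_threatened(only_isis, sp)$accepted_name)
})
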