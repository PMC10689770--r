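regions8 <- sim_config()$region_names

test_that("region assignment validates labels and reports unmapped", {
  map <- tibble::tibble(country = c("A", "B"), region = regions8[1:2])
  out <- assign_regions(c("A", "B"), map)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_unmapped"), 0L)
  expect_warning(out2 <- assign_regions(c("A", "B", "Z"), map), "without")
  expect_equal(attr(out2, "n_unmapped"), 1L)
  bad <- tibble::tibble(country = "A", region = "Atlantis")
  expect_error(assign_regions("A", bad), "outside")
})

test_that("flow matrix counts donor/recipient region triples", {
  sp <- tibble::tibble(
    accepted_name = "s1", class = "bird",
    native_extant = list(c("AF1", "AF2")),
    native_possibly_extant = list(character(0)),
    extinct_range = list(character(0)),
    possibly_extinct = list(character(0)),
    introduced = list(character(0)))
  map <- tibble::tibble(country = c("AF1", "AF2", "EU1"),
                        region = c("Africa", "Africa", "Europe"))
  cl <- classify_records(
    tibble::tibble(accepted_name = "s1", country = c("EU1", "AF2", "AF1")),
    sp)
  m <- flow_matrix(cl, sp, map)
  # alien-traded in Europe; AF1/AF2 are native records -> no flows from them
  expect_equal(m["Africa", "Europe"], 1L)
  expect_equal(sum(m), 1L)
  # a species alien-traded within its native region hits the diagonal
  cl2 <- classify_records(
    tibble::tibble(accepted_name = "s1", country = "AF3"),
    sp)
  map2 <- rbind(map, tibble::tibble(country = "AF3", region = "Africa"))
  m2 <- flow_matrix(cl2, sp, map2)
  expect_equal(m2["Africa", "Africa"], 1L)
  # no alien records -> zero matrix
  m0 <- flow_matrix(cl[cl$label == "native", ], sp, map)
  expect_equal(sum(m0), 0L)
})

test_that("flow matrix equals the exhaustive triple-enumeration oracle", {
  keep <- head(unique(tiny$classified$accepted_name), 25)
  cl <- tiny$classified[tiny$classified$accepted_name %in% keep, ]
  sp <- tiny$species[tiny$species$accepted_name %in% keep, ]
  map <- tiny$world[, c("country", "region")]
  m <- flow_matrix(cl, sp, map)
  oracle <- oracle_flow(cl, sp, map, regions8, keep = keep)
  expect_equal(unclass(m)[regions8, regions8], oracle[regions8, regions8],
               ignore_attr = TRUE)
})

test_that("totals conserve and established flows nest within all flows", {
  map <- tiny$world[, c("country", "region")]
  m <- flow_matrix(tiny$classified, tiny$species, map)
  rt <- region_totals(m)
  expect_equal(sum(rt$donor), rt$grand_total)
  expect_equal(sum(rt$recipient), rt$grand_total)
  st <- species_alien_status(tiny$classified)
  est <- head(st$accepted_name[st$alien_anywhere], 40)
  me <- flow_matrix(tiny$classified, tiny$species, map,
                    filter = "established", established = est)
  expect_true(all(me <= m))
  expect_error(flow_matrix(tiny$classified, tiny$species, map,
                           filter = "established"), "established")
})

test_that("chord edge export round-trips the matrix", {
  map <- tiny$world[, c("country", "region")]
  m <- flow_matrix(tiny$classified, tiny$species, map)
  edges <- export_chord(m)
  expect_equal(nrow(edges), sum(m > 0))
  back <- chord_to_matrix(edges)
  expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
  empty <- export_chord(chord_to_matrix(edges[0, ]))
  expect_equal(nrow(empty), 0)
})
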