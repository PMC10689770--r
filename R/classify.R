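#' Native range of each species as a country set
#'
#' The native range is the union of the four native presence categories
#' (native extant, native possibly extant, extinct, possibly extinct);
#' countries where the species has only an introduced presence are
#' excluded. An empty union marks the species as lacking range data.
#'
#' @param species Species master with the list-columns `native_extant`,
#'   `native_possibly_extant`, `extinct_range`, `possibly_extinct`.
#' @return The input tibble with an added list-column `native_countries`.
#' @examples
#' sp <- tibble::tibble(
#'   accepted_name = "Testus aa",
#'   native_extant = list("FR"), native_possibly_extant = list(character(0)),
#'   extinct_range = list("ES"), possibly_extinct = list(character(0)),
#'   introduced = list("US"))
#' native_range(sp)$native_countries[[1]]
#' @export
native_range <- function(species) {
  assert_columns(species, c("native_extant", "native_possibly_extant",
                            "extinct_range", "possibly_extinct"))
  species$native_countries <- native_range_sets(species)
  species
}

#' Classify traded records as alien or native
#'
#' Labels every (species, country) observation: `alien` when the country is
#' outside the species' native range, `native` when inside, and
#' `unknown-range` when the species has no range data (such records are
#' excluded from richness counts downstream but retained here).
#'
#' @param records Clean records with `accepted_name` and `country`.
#' @param species Species master (range list-columns as in
#'   [native_range()]).
#' @return The records tibble with an added `label` column.
#' @export
classify_records <- function(records, species) {
  assert_columns(records, c("accepted_name", "country"))
  missing <- setdiff(records$accepted_name, species$accepted_name)
  if (length(missing) > 0) {
    abort(sprintf("species absent from master: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  sp <- native_range(species)
  nat_long <- tibble(
    accepted_name = rep(sp$accepted_name, lengths(sp$native_countries)),
    country = unlist(sp$native_countries), .is_native = TRUE)
  empty_range <- sp$accepted_name[lengths(sp$native_countries) == 0]
  records <- records %>%
    left_join(nat_long, by = c("accepted_name", "country"))
  records$label <- ifelse(records$accepted_name %in% empty_range,
                          "unknown-range",
                          ifelse(is.na(records$.is_native), "alien",
                                 "native"))
  records$.is_native <- NULL
  records
}

#' Species-level alien-trade status flags
#'
#' Summarises classified records per species: whether it was traded as an
#' alien anywhere, only within its native range, or both inside and outside
#' it.
#'
#' @param classified Output of [classify_records()].
#' @return A tibble with `accepted_name`, `alien_anywhere`, `native_only`,
#'   `both_alien_and_native`, `unknown_range_only`.
#' @export
species_alien_status <- function(classified) {
  assert_columns(classified, c("accepted_name", "label"))
  classified %>%
    group_by(.data$accepted_name) %>%
    summarise(
      alien_anywhere = any(.data$label == "alien"),
      native_only = !any(.data$label == "alien") &
        any(.data$label == "native"),
      both_alien_and_native = any(.data$label == "alien") &
        any(.data$label == "native"),
      unknown_range_only = all(.data$label == "unknown-range"),
      .groups = "drop")
}

#' Per-country richness summary (the regression table)
#'
#' Counts distinct species per country for each class and in total, split
#' into alien richness (colonization pressure), native richness and
#' established-alien richness, then joins the country covariates. Species
#' with unknown range are excluded from all richness counts.
#'
#' @param classified Output of [classify_records()].
#' @param species Species master (for the class of each species).
#' @param world Country covariate table.
#' @param establishment Optional establishment records (`accepted_name`,
#'   `country`); established-alien richness is 0 when omitted.
#' @return A tibble with one row per country x class (classes plus
#'   `"total"`): `alien_richness`, `native_richness`,
#'   `establishment_richness`, the country covariates, and
#'   `congeneric_richness` resolved per class.
#' @export
country_richness <- function(classified, species, world,
                             establishment = NULL) {
  assert_columns(classified, c("accepted_name", "country", "label"))
  cls <- species$class[match(classified$accepted_name,
                             species$accepted_name)]
  known <- classified[classified$label != "unknown-range", ]
  known$class <- cls[classified$label != "unknown-range"]

  count_block <- function(df, value_name) {
    tot <- df %>%
      group_by(.data$country) %>%
      summarise(n = n_distinct(.data$accepted_name), .groups = "drop") %>%
      mutate(class = "total")
    per <- df %>%
      group_by(.data$country, .data$class) %>%
      summarise(n = n_distinct(.data$accepted_name), .groups = "drop")
    out <- bind_rows(per, tot)
    names(out)[names(out) == "n"] <- value_name
    out
  }
  alien <- count_block(known[known$label == "alien", ], "alien_richness")
  native <- count_block(known[known$label == "native", ], "native_richness")

  classes <- c(sort(unique(species$class)), "total")
  grid <- tidyr::expand_grid(country = world$country, class = classes)
  out <- grid %>%
    left_join(alien, by = c("country", "class")) %>%
    left_join(native, by = c("country", "class"))

  if (!is.null(establishment) && nrow(establishment) > 0) {
    est <- establishment
    est$class <- species$class[match(est$accepted_name,
                                     species$accepted_name)]
    est <- est[!is.na(est$class), ]
    estc <- count_block(est, "establishment_richness")
    out <- left_join(out, estc, by = c("country", "class"))
  } else {
    out$establishment_richness <- 0L
  }
  out <- out %>%
    mutate(across(c("alien_richness", "native_richness",
                    "establishment_richness"),
                  ~ as.integer(tidyr::replace_na(.x, 0L)))) %>%
    left_join(world, by = "country")
  cong_col <- paste0("congeneric_", out$class)
  cong_col[out$class == "total"] <- NA
  out$congeneric_richness <- vapply(seq_len(nrow(out)), function(i) {
    if (is.na(cong_col[i])) {
      sum(unlist(out[i, paste0("congeneric_",
                               setdiff(classes, "total"))]))
    } else out[[cong_col[i]]][i]
  }, numeric(1))
  out
}

#' Venn-region counts across the four trade sources
#'
#' Computes the 15 disjoint intersection regions of the four per-source
#' species sets, the union, and the number and share of species unique to a
#' single source.
#'
#' @param source_sets A named list of exactly four character vectors of
#'   species names (one per source).
#' @return A list with `regions` (tibble `membership`, `n`), `union_size`,
#'   `unique_n` and `unique_share` (percent, one decimal, half-up).
#' @examples
#' venn_counts(list(A = c("s1", "s2"), B = "s2", C = character(0),
#'                  D = character(0)))$unique_n
#' @export
venn_counts <- function(source_sets) {
  if (length(source_sets) != 4) {
    abort("exactly four source sets are required.")
  }
  sets <- lapply(source_sets, unique)
  all_sp <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_sp %in% s, logical(length(all_sp)))
  if (length(all_sp) == 1) memb <- matrix(memb, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(1:4, function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  regions <- tibble(membership = combos,
                    n = as.integer(table(factor(pattern,
                                                levels = combos))))
  unique_n <- sum(regions$n[regions$membership %in% names(sets)])
  list(regions = regions,
       union_size = length(all_sp),
       unique_n = unique_n,
       unique_share = round_half_up(100 * unique_n /
                                      max(1, length(all_sp)), 1))
}

#' Headline share metrics from species totals
#'
#' Computes the reported percentage and ratio metrics from count totals:
#' traded species as a share of extant species, aliens as a share of traded
#' species, established aliens as a share of traded aliens, traded species
#' as a share of established species, species traded only natively, and
#' aliens also traded within their native range. Percentages are rounded
#' half-up to one decimal; zero denominators yield `NA` and are flagged.
#'
#' @param n_traded,n_extant,n_alien,n_established_traded,n_established_total,n_native_only,n_both
#'   Scalar counts; any may be `NA` to skip its metrics.
#' @return A tibble with `metric`, `numerator`, `denominator`, `value`
#'   (percent) and `defined`.
#' @examples
#' share_metrics(n_traded = 7780, n_alien = 6664)$value[2]
#' @export
share_metrics <- function(n_traded = NA, n_extant = NA, n_alien = NA,
                          n_established_traded = NA,
                          n_established_total = NA,
                          n_native_only = NA, n_both = NA) {
  rows <- tibble(
    metric = c("traded_of_extant", "alien_of_traded",
               "established_of_alien", "traded_of_established",
               "native_only_of_traded", "both_of_alien"),
    numerator = c(n_traded, n_alien, n_established_traded,
                  n_established_traded, n_native_only, n_both),
    denominator = c(n_extant, n_traded, n_alien, n_established_total,
                    n_traded, n_alien))
  rows$defined <- !is.na(rows$numerator) & !is.na(rows$denominator) &
    rows$denominator > 0
  rows$value <- ifelse(rows$defined,
                       round_half_up(100 * rows$numerator /
                                       rows$denominator, 1), NA_real_)
  rows
}
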