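#' Match an established-species list against traded aliens
#'
#' Established-by-trade species are the intersection of the established
#' list with the species traded as aliens. Reports the intersection and its
#' share of all established species.
#'
#' @param established Character vector (or data frame with
#'   `accepted_name`) of established species.
#' @param traded_alien Character vector (or data frame with
#'   `accepted_name`) of species traded as aliens anywhere.
#' @return A list: `established_by_trade` (character vector), `n_matched`,
#'   `n_established`, `share_of_established` (percent, one decimal).
#' @examples
#' match_established(c("a", "b"), c("b", "c"))$established_by_trade
#' @export
match_established <- function(established, traded_alien) {
  if (is.data.frame(established)) established <- established$accepted_name
  if (is.data.frame(traded_alien)) traded_alien <- traded_alien$accepted_name
  established <- unique(established)
  hit <- intersect(established, unique(traded_alien))
  list(established_by_trade = hit,
       n_matched = length(hit),
       n_established = length(established),
       share_of_established = if (length(established) > 0)
         round_half_up(100 * length(hit) / length(established), 1)
       else NA_real_)
}

#' Per-species trade breadth
#'
#' For every traded species, counts the distinct countries with any trade
#' record and sums the land areas of those countries. The area sum is the
#' default "trade area" metric; countries with missing area are treated as
#' zero with a warning.
#'
#' @param classified Classified records (`accepted_name`, `country`).
#' @param world Country table with `area_km2`.
#' @param species Species master (for `class`).
#' @param established Optional character vector of established species used
#'   to set the `established` flag.
#' @return A tibble: `accepted_name`, `class`, `established` (0/1),
#'   `n_trade_countries`, `trade_area_km2`.
#' @export
trade_breadth <- function(classified, world, species, established = NULL) {
  assert_columns(classified, c("accepted_name", "country"))
  area <- world$area_km2[match(classified$country, world$country)]
  if (anyNA(area)) {
    warn(sprintf("%d record(s) reference countries with no area; treated as 0.",
                 sum(is.na(area))))
    area[is.na(area)] <- 0
  }
  classified$.area <- area
  out <- classified %>%
    distinct(.data$accepted_name, .data$country, .data$.area) %>%
    group_by(.data$accepted_name) %>%
    summarise(n_trade_countries = n(),
              trade_area_km2 = sum(.data$.area), .groups = "drop")
  out$class <- species$class[match(out$accepted_name,
                                   species$accepted_name)]
  out$established <- as.integer(out$accepted_name %in%
                                  (established %||% character(0)))
  out[, c("accepted_name", "class", "established", "n_trade_countries",
          "trade_area_km2")]
}

#' Breadth comparison between established and unestablished species
#'
#' Per class: mean and sample standard deviation (n - 1) of a breadth
#' metric in the established and unestablished groups, and the ratio of
#' group means rounded to two decimals. Degenerate groups (empty, or
#' single species where the sd is undefined) are flagged.
#'
#' @param breadth A [trade_breadth()] table.
#' @param metric Column to compare: `"n_trade_countries"` (default) or
#'   `"trade_area_km2"`.
#' @return A tibble per class: group means, sds, ns, `ratio` and
#'   `degenerate`.
#' @export
breadth_summary <- function(breadth, metric = "n_trade_countries") {
  assert_columns(breadth, c("class", "established", metric))
  breadth %>%
    group_by(.data$class) %>%
    summarise(
      mean_established = mean(.data[[metric]][.data$established == 1]),
      sd_established = sd(.data[[metric]][.data$established == 1]),
      n_established = sum(.data$established == 1),
      mean_unestablished = mean(.data[[metric]][.data$established == 0]),
      sd_unestablished = sd(.data[[metric]][.data$established == 0]),
      n_unestablished = sum(.data$established == 0),
      .groups = "drop") %>%
    mutate(
      ratio = ifelse(is.nan(.data$mean_established) |
                       is.nan(.data$mean_unestablished) |
                       .data$mean_unestablished == 0, NA_real_,
                     round_half_up(.data$mean_established /
                                     .data$mean_unestablished, 2)),
      degenerate = .data$n_established < 2 | .data$n_unestablished < 2)
}
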