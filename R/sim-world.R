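#' Generate a synthetic world of countries
#'
#' Draws a country table with one row per country: realm and economic-region
#' membership, insularity, and the socio-economic and environmental
#' covariates used downstream as regression predictors. Covariates come from
#' documented log-normal / beta / realm-shifted-normal families; income
#' class is assigned by GDP-per-capita quartile so that all four strata are
#' populated.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `country`, `name`, `realm`, `region`,
#'   `insularity`, `income_class`, `area_km2`, `population`, `gdp`,
#'   `gdp_pc`, `pop_density`, `trade_value`, `mean_temperature`,
#'   `mean_precipitation`, `congeneric_mammal`, `congeneric_bird`,
#'   `congeneric_reptile`, `congeneric_amphibian`, `sampling_effort`.
#' @examples
#' world <- simulate_world(sim_config(n_countries = 40, seed = 7))
#' dplyr::count(world, realm)
#' @export
simulate_world <- function(config) {
  validate_config(config)
  n <- config$n_countries
  cells <- realm_region_cells(config)
  with_stream(config$seed, "world", {
    # allocate countries to (realm, region) cells by largest remainder,
    # guaranteeing every cell at least one country when n permits
    raw <- cells$w / sum(cells$w) * n
    cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
      idx <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[idx] <- cnt[idx] + 1L
    }
    if (n >= nrow(cells)) {
      while (any(cnt == 0)) {
        give <- which.max(cnt)
        need <- which(cnt == 0)[1]
        cnt[give] <- cnt[give] - 1L
        cnt[need] <- cnt[need] + 1L
      }
    }
    ord <- sample.int(n)  # shuffle so country ids are not realm-blocked
    realm <- rep(cells$realm, cnt)[ord]
    region <- rep(cells$region, cnt)[ord]

    area_km2 <- rlnorm(n, 11.5, 2)
    population <- rlnorm(n, 15.8, 1.8)
    gdp_pc <- rlnorm(n, 9.2, 1.3)
    gdp <- gdp_pc * population
    trade_value <- gdp * rlnorm(n, -1.5, 0.8)
    p_isl <- ifelse(region == "Oceania", 0.8, 0.18)
    insularity <- rbinom(n, 1, p_isl)
    temp_base <- c(Afrotropics = 24, Australasia = 21, `Indo-Malay` = 25,
                   Nearctic = 8, Neotropics = 23, Palaearctic = 9,
                   Oceania = 24)
    mt <- temp_base[realm]
    mt[is.na(mt)] <- 15
    mean_temperature <- unname(mt) + rnorm(n, 0, 3)
    mean_precipitation <- rlnorm(n, 6.9, 0.6)
    cong_mu <- c(mammal = 60, bird = 150, reptile = 70, amphibian = 40)
    cong <- lapply(cong_mu, function(mu) rnbinom(n, size = 1.5, mu = mu))
    sampling_effort <- stats::rbeta(n, 2, 10)

    q <- stats::quantile(gdp_pc, c(0.25, 0.5, 0.75))
    income_class <- cut(gdp_pc, c(-Inf, q, Inf),
                        labels = c("low", "lower-middle", "upper-middle",
                                   "high"))

    tibble(
      country = sprintf("C%03d", seq_len(n)),
      name = sprintf("Country %03d", seq_len(n)),
      realm = realm, region = region,
      insularity = insularity,
      income_class = as.character(income_class),
      area_km2 = area_km2, population = population, gdp = gdp,
      gdp_pc = gdp_pc, pop_density = population / area_km2,
      trade_value = trade_value,
      mean_temperature = mean_temperature,
      mean_precipitation = mean_precipitation,
      congeneric_mammal = cong$mammal,
      congeneric_bird = cong$bird,
      congeneric_reptile = cong$reptile,
      congeneric_amphibian = cong$amphibian,
      sampling_effort = sampling_effort
    )
  })
}

# (realm, region) cells with sampling weights; curated for the default
# names, generic pairing otherwise
realm_region_cells <- function(config) {
  def_realms <- c("Afrotropics", "Australasia", "Indo-Malay", "Nearctic",
                  "Neotropics", "Palaearctic", "Oceania")
  def_regions <- c("South and East Asia", "Mideast and Central Asia",
                   "Africa", "Europe", "North America", "Central America",
                   "South America", "Oceania")
  if (identical(config$realm_names, def_realms) &&
      identical(config$region_names, def_regions)) {
    return(data.frame(
      realm = c("Afrotropics", "Australasia", "Indo-Malay", "Nearctic",
                "Neotropics", "Neotropics", "Palaearctic", "Palaearctic",
                "Palaearctic", "Oceania"),
      region = c("Africa", "Oceania", "South and East Asia", "North America",
                 "Central America", "South America", "Europe",
                 "Mideast and Central Asia", "South and East Asia",
                 "Oceania"),
      w = c(0.20, 0.06, 0.12, 0.03, 0.10, 0.08, 0.22, 0.10, 0.04, 0.05)
    ))
  }
  k <- max(length(config$realm_names), length(config$region_names))
  data.frame(
    realm = rep(config$realm_names, length.out = k),
    region = rep(config$region_names, length.out = k),
    w = rep(1, k)
  )
}
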