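#' Simulation configuration for a synthetic trade world
#'
#' Builds the configuration object consumed by [simulate_world()],
#' [simulate_species()], [simulate_trade()] and [simulate_establishment()].
#' Defaults emulate the global live vertebrate trade at full scale: 7,780
#' species across the four terrestrial vertebrate classes, 193 countries in
#' 7 biogeographic realms and 8 economic regions, and four overlapping data
#' sources whose per-source species totals match the published marginals.
#'
#' @param n_countries Number of countries in the world. Default 193.
#' @param n_species_per_class Named integer vector of species counts for the
#'   classes `mammal`, `bird`, `reptile`, `amphibian`.
#' @param realm_names Character vector of biogeographic realm names
#'   (default the 7 continental realms).
#' @param region_names Character vector of the 8 economic regions.
#' @param source_marginals Named integer vector: target number of distinct
#'   species contributed by each source (`CITES`, `LEMIS`, `ISIS`, `OTAPS`).
#' @param p_unique Fraction of species that belong to exactly one source.
#' @param overlap_control Gamma shape controlling how concentrated
#'   multi-source membership is on "popular" species; larger values spread
#'   co-membership more evenly.
#' @param p_alien_trade Probability that a single trade-country draw for a
#'   species falls outside its native range.
#' @param import_attraction Named log-linear weights (over standardized
#'   log population, log commercial trade value and log GDP per capita)
#'   tilting which countries receive alien-trade draws; the shared
#'   importing-power factor behind cross-taxa richness correlations.
#' @param breadth Named list `size`, `mu`: negative-binomial parameters for
#'   the number of trading countries per species (breadth is `1 + NB`).
#' @param establishment_logit Named vector `intercept`, `slope`: the
#'   species-level logistic model of establishment on number of trading
#'   countries.
#' @param p_establish_other Establishment probability for species never
#'   traded as aliens (these pad the established pool so that traded species
#'   form only part of it, as in real establishment databases).
#' @param country_model List with `intercept`, `beta` (named vector over the
#'   nine country-level predictors), `realm_sd` and `resid_sd`: the
#'   log-linear model from which country-level establishment richness is
#'   drawn on the `log1p` scale, with a realm random intercept.
#' @param noise Named list of rates: `synonym` (a record carries a synonym
#'   rather than the accepted name), `typo` (an extra record carries a
#'   corrupted name), `junk` (an online listing contains no species key).
#' @param qc Named list of planting rates for records that quality control
#'   must remove: `duplicate`, `same_importer_exporter`, `missing_name`,
#'   `hybrid`, `nonlive`, `isis_threatened`.
#' @param native_range_size Integer vector `c(min, max)` for native-range
#'   country-set sizes.
#' @param n_extant Total extant species count used as the denominator of the
#'   traded-share metric. Default 34285.
#' @param scale Convenience multiplier applied to `n_species_per_class` and
#'   `source_marginals` (useful for small test worlds).
#' @param seed Integer seed; every generator derives an independent
#'   named substream from it.
#'
#' @return An object of class `colpress_config` (a validated named list).
#' @examples
#' cfg <- sim_config(scale = 0.05, n_countries = 40, seed = 1)
#' cfg$source_marginals
#' @export
sim_config <- function(n_countries = 193,
                       n_species_per_class = c(mammal = 1247, bird = 3451,
                                               reptile = 2278, amphibian = 804),
                       realm_names = c("Afrotropics", "Australasia",
                                       "Indo-Malay", "Nearctic", "Neotropics",
                                       "Palaearctic", "Oceania"),
                       region_names = c("South and East Asia",
                                        "Mideast and Central Asia", "Africa",
                                        "Europe", "North America",
                                        "Central America", "South America",
                                        "Oceania"),
                       source_marginals = c(CITES = 2371, LEMIS = 3908,
                                            ISIS = 3116, OTAPS = 5053),
                       p_unique = 0.451,
                       overlap_control = 1,
                       p_alien_trade = 0.63,
                       import_attraction = c(population = 0.5,
                                             trade_value = 0.5,
                                             gdp_pc = 0.3),
                       breadth = list(size = 0.31, mu = 9.6),
                       establishment_logit = c(intercept = -3.21, slope = 0.08),
                       p_establish_other = 0.2,
                       country_model = list(
                         intercept = 2.5,
                         beta = c(area = 0.10, pop_density = 0.10,
                                  gdp_pc = 0.20, colonization_pressure = 0.35,
                                  insularity = 0.25, mean_temperature = 0.00,
                                  mean_precipitation = 0.05,
                                  congeneric_richness = 0.05,
                                  sampling_effort = 0.15),
                         realm_sd = 0.25,
                         resid_sd = 0.40),
                       noise = list(synonym = 0.30, typo = 0.05, junk = 0.20),
                       qc = list(duplicate = 0.03,
                                 same_importer_exporter = 0.02,
                                 missing_name = 0.01, hybrid = 0.01,
                                 nonlive = 0.05, isis_threatened = 0.02),
                       native_range_size = c(2L, 15L),
                       n_extant = 34285,
                       scale = 1,
                       seed = 1L) {
  if (scale != 1) {
    n_species_per_class <- setNames(
      pmax(4L, round(n_species_per_class * scale)),
      names(n_species_per_class))
    # rescale marginals against the shrunken pool, keeping source proportions
    tot <- sum(n_species_per_class)
    source_marginals <- setNames(
      pmax(2L, round(source_marginals / 7780 * tot)),
      names(source_marginals))
  }
  cfg <- list(
    n_countries = as.integer(n_countries),
    n_species_per_class = n_species_per_class,
    realm_names = realm_names,
    region_names = region_names,
    source_marginals = source_marginals,
    p_unique = p_unique,
    overlap_control = overlap_control,
    p_alien_trade = p_alien_trade,
    import_attraction = import_attraction,
    breadth = breadth,
    establishment_logit = establishment_logit,
    p_establish_other = p_establish_other,
    country_model = country_model,
    noise = noise,
    qc = qc,
    native_range_size = as.integer(native_range_size),
    n_extant = n_extant,
    seed = as.integer(seed)
  )
  class(cfg) <- "colpress_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "colpress_config"))
  if (cfg$n_countries < 4) abort("`n_countries` must be at least 4.")
  if (any(cfg$n_species_per_class <= 0)) abort("species counts must be positive.")
  if (anyDuplicated(cfg$realm_names) || anyDuplicated(cfg$region_names)) {
    abort("realm or region names collide: names must be unique.")
  }
  if (length(intersect(cfg$realm_names, cfg$region_names)) > 0 &&
      !identical(sort(intersect(cfg$realm_names, cfg$region_names)), "Oceania")) {
    abort("realm and region name sets collide beyond the shared 'Oceania' label.")
  }
  probs <- c(cfg$p_unique, cfg$p_alien_trade, cfg$p_establish_other,
             unlist(cfg$noise), unlist(cfg$qc))
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1].")
  if (any(cfg$source_marginals > sum(cfg$n_species_per_class))) {
    abort("`source_marginals` cannot exceed the species pool size.")
  }
  if (any(cfg$source_marginals < 1)) abort("`source_marginals` must be positive.")
  if (length(cfg$country_model$beta) != 9) {
    abort("`country_model$beta` must cover the nine country-level predictors.")
  }
  if (cfg$country_model$realm_sd < 0 || cfg$country_model$resid_sd <= 0) {
    abort("country-model standard deviations must be non-negative (residual > 0).")
  }
  if (cfg$native_range_size[1] < 1 ||
      cfg$native_range_size[2] >= cfg$n_countries) {
    abort("`native_range_size` must lie within [1, n_countries - 1].")
  }
  cfg
}

#' Read or write a simulation configuration as YAML
#'
#' @param path File path.
#' @return `read_sim_config()` returns a `colpress_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("n_species_per_class", "source_marginals",
               "establishment_logit", "import_attraction")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$country_model$beta)) {
    raw$country_model$beta <- unlist(raw$country_model$beta)
  }
  if (!is.null(raw$native_range_size)) {
    raw$native_range_size <- as.integer(unlist(raw$native_range_size))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `colpress_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "colpress_config"))
  yaml::write_yaml(rapply(unclass(config), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }, classes = "numeric", how = "replace"), path)
  invisible(path)
}

#' @export
print.colpress_config <- function(x, ...) {
  cat("<colpress_config>\n")
  cat("  countries:", x$n_countries,
      "| species:", sum(x$n_species_per_class),
      "| seed:", x$seed, "\n")
  cat("  sources:", paste(sprintf("%s=%d", names(x$source_marginals),
                                  x$source_marginals), collapse = " "), "\n")
  invisible(x)
}
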