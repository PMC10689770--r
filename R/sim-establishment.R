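#' Generate synthetic establishment data with a recoverable truth ledger
#'
#' Draws establishment from the two generative layers the downstream
#' analyses assume. At the species level, every species traded as an alien
#' somewhere establishes with probability
#' `plogis(intercept + slope * n_trade_countries)`; species traded only
#' within their native range establish with probability
#' `p_establish_other`, so the established pool is wider than the
#' traded-alien pool. Established aliens are then placed in a subset of the
#' countries where they were traded as aliens. Independently, a per-country,
#' per-class establishment-richness response is drawn from the log-linear
#' country model (`log1p` scale, standardized predictors, realm random
#' intercepts) for parameter-recovery studies of the multimodel inference.
#'
#' @param classified Classified records from [classify_records()].
#' @param species Species master table.
#' @param world Country table.
#' @param config A [sim_config()] object.
#' @return A list with elements `records` (tibble `accepted_name`,
#'   `country`), `species_flags` (tibble `accepted_name`, `class`,
#'   `alien_anywhere`, `n_trade_countries`, `established`),
#'   `country_model_richness` (tibble `country`, `class`, `richness`) and
#'   `truth` (the parameter values used, including the realized realm
#'   intercepts).
#' @export
simulate_establishment <- function(classified, species, world, config) {
  validate_config(config)
  assert_columns(classified, c("accepted_name", "country", "label"))
  with_stream(config$seed, "establishment", {
    a <- config$establishment_logit[["intercept"]]
    b <- config$establishment_logit[["slope"]]

    traded <- classified[classified$label != "unknown-range", ]
    per_sp <- traded %>%
      group_by(.data$accepted_name) %>%
      summarise(n_trade_countries = n_distinct(.data$country),
                alien_anywhere = any(.data$label == "alien"),
                .groups = "drop") %>%
      left_join(species[, c("accepted_name", "class")], by = "accepted_name")

    p <- ifelse(per_sp$alien_anywhere,
                plogis(a + b * per_sp$n_trade_countries),
                config$p_establish_other)
    per_sp$established <- rbinom(nrow(per_sp), 1, p) == 1

    est_alien <- per_sp$accepted_name[per_sp$established & per_sp$alien_anywhere]
    alien_rec <- traded[traded$label == "alien" &
                          traded$accepted_name %in% est_alien, ]
    rec_by_sp <- split(alien_rec$country, alien_rec$accepted_name)
    records <- bind_rows(lapply(names(rec_by_sp), function(nm) {
      cc <- unique(rec_by_sp[[nm]])
      keep <- cc[runif(length(cc)) < 0.3]
      if (length(keep) == 0) keep <- cc[sample.int(length(cc), 1)]
      tibble(accepted_name = nm, country = keep)
    }))
    # established never-alien species: establishment records outside trade,
    # in countries where the species is not native
    other <- per_sp$accepted_name[per_sp$established & !per_sp$alien_anywhere]
    if (length(other) > 0) {
      nat <- native_range_sets(species[match(other, species$accepted_name), ])
      extra <- bind_rows(lapply(seq_along(other), function(i) {
        pool <- setdiff(world$country, nat[[i]])
        tibble(accepted_name = other[i],
               country = sample(pool, min(length(pool), sample(1:2, 1))))
      }))
      records <- bind_rows(records, extra)
    }

    cm <- draw_country_model(classified, species, world, config)

    list(records = records,
         species_flags = per_sp,
         country_model_richness = cm$richness,
         truth = list(establishment_logit = c(intercept = a, slope = b),
                      p_establish_other = config$p_establish_other,
                      country_model = config$country_model,
                      realm_intercepts = cm$realm_intercepts,
                      seed = config$seed))
  })
}

# per-country, per-class establishment richness drawn on the log1p scale
# from standardized predictors + realm intercept + residual noise
draw_country_model <- function(classified, species, world, config) {
  cmod <- config$country_model
  realms <- sort(unique(world$realm))
  u <- rnorm(length(realms), 0, cmod$realm_sd)
  names(u) <- realms
  classes <- names(config$n_species_per_class)
  rich <- bind_rows(lapply(classes, function(cl) {
    X <- country_design(classified, world, cl, species)
    eta <- cmod$intercept + as.vector(X %*% cmod$beta[colnames(X)]) +
      u[world$realm] + rnorm(nrow(world), 0, cmod$resid_sd)
    tibble(country = world$country, class = cl,
           richness = pmax(0, round(expm1(eta))))
  }))
  list(richness = rich, realm_intercepts = u)
}

# the nine-predictor standardized design used by the generating model;
# mirrors the transform conventions of the inference stage
country_design <- function(classified, world, cl, species) {
  alien <- classified[classified$label == "alien", ]
  cls <- species$class[match(alien$accepted_name, species$accepted_name)]
  alien <- alien[!is.na(cls) & cls == cl, ]
  cp <- table(factor(alien$country, levels = world$country))
  cong <- world[[paste0("congeneric_", cl)]]
  raw <- cbind(
    area = log(world$area_km2),
    pop_density = log(world$pop_density),
    gdp_pc = log(world$gdp_pc),
    colonization_pressure = log1p(as.numeric(cp)),
    insularity = world$insularity,
    mean_temperature = world$mean_temperature,
    mean_precipitation = log(world$mean_precipitation),
    congeneric_richness = log1p(cong),
    sampling_effort = world$sampling_effort
  )
  std <- scale(raw[, colnames(raw) != "insularity"])
  out <- cbind(std, insularity = raw[, "insularity"])
  out[, colnames(raw)]
}

#' Write or read the simulation truth ledger
#'
#' The truth ledger records the parameter values a synthetic world was
#' generated from (establishment logit, country-model coefficients and
#' variance components, realized realm intercepts), so recovery tests can
#' compare estimates against known truth.
#'
#' @param truth The `truth` element returned by [simulate_establishment()].
#' @param path File path for the YAML ledger.
#' @return `write_truth_ledger()` returns `path` invisibly;
#'   `read_truth_ledger()` returns the ledger list.
#' @export
write_truth_ledger <- function(truth, path) {
  yaml::write_yaml(rapply(truth, function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }, how = "replace"), path)
  invisible(path)
}

#' @rdname write_truth_ledger
#' @export
read_truth_ledger <- function(path) {
  led <- yaml::read_yaml(path)
  led$establishment_logit <- unlist(led$establishment_logit)
  led$country_model$beta <- unlist(led$country_model$beta)
  led$realm_intercepts <- unlist(led$realm_intercepts)
  led
}
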