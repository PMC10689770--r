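#' Generate a synthetic species master table
#'
#' Creates the species pool with full taxonomy (class/order/family/genus),
#' an IUCN threat category, and country-set range fields: native presence is
#' sampled as a cluster of countries within one home realm (with a small
#' spillover probability into a second realm), split across the four native
#' presence categories; a disjoint introduced set is added for a fraction of
#' species.
#'
#' @param world Country table from [simulate_world()].
#' @param config A [sim_config()] object.
#' @return A tibble with one row per species: `accepted_name`, `class`,
#'   `order`, `family`, `genus`, `iucn_category`, list-columns
#'   `native_extant`, `native_possibly_extant`, `extinct_range`,
#'   `possibly_extinct`, `introduced`, and `home_realm`.
#' @examples
#' cfg <- sim_config(scale = 0.02, n_countries = 30, seed = 1)
#' world <- simulate_world(cfg)
#' sp <- simulate_species(world, cfg)
#' nrow(sp)
#' @export
simulate_species <- function(world, config) {
  validate_config(config)
  assert_columns(world, c("country", "realm"))
  counts <- config$n_species_per_class
  with_stream(config$seed, "species", {
    per_class <- lapply(names(counts), function(cl) {
      n <- counts[[cl]]
      n_gen <- min(790L, max(2L, ceiling(n / 6)))
      gen_idx <- sort(sample.int(n_gen, n, replace = TRUE))
      gen_names <- synth_genus(class_offset(cl) + seq_len(n_gen))
      n_fam <- max(1L, ceiling(n_gen / 8))
      fam_of_gen <- sprintf("%sidae_%02d", toupper(substr(cl, 1, 2)),
                            1L + (seq_len(n_gen) - 1L) %% n_fam)
      n_ord <- max(1L, ceiling(n_fam / 6))
      ord_of_fam <- sprintf("%sformes_%02d", toupper(substr(cl, 1, 2)),
                            1L + (seq_len(n_fam) - 1L) %% n_ord)
      epi_rank <- stats::ave(gen_idx, gen_idx, FUN = seq_along)
      tibble(
        accepted_name = paste(gen_names[gen_idx],
                              synth_epithet(epi_rank + 37L)),
        class = cl,
        genus = gen_names[gen_idx],
        family = fam_of_gen[gen_idx],
        order = ord_of_fam[match(fam_of_gen[gen_idx], fam_of_gen)]
      )
    })
    sp <- bind_rows(per_class)
    n <- nrow(sp)
    sp$iucn_category <- sample(
      c("LC", "NT", "VU", "EN", "CR", "DD"), n, replace = TRUE,
      prob = c(0.55, 0.12, 0.12, 0.09, 0.05, 0.07))

    realms <- split(world$country, world$realm)
    realm_names <- names(realms)
    home <- sample(realm_names, n, replace = TRUE)
    rng <- config$native_range_size
    ranges <- lapply(seq_len(n), function(i) {
      pool <- realms[[home[i]]]
      r <- sample(rng[1]:rng[2], 1)
      nat <- sample(pool, min(r, length(pool)))
      if (runif(1) < 0.15) {  # spillover into one neighbouring realm
        other <- realms[[sample(setdiff(realm_names, home[i]), 1)]]
        nat <- union(nat, sample(other, min(length(other), sample(1:2, 1))))
      }
      nat
    })
    presence <- lapply(ranges, function(nat) {
      ext <- character(0); poss <- character(0); pex <- character(0)
      if (length(nat) > 2 && runif(1) < 0.10) {
        ext <- nat[1]; nat <- nat[-1]
      }
      if (length(nat) > 2 && runif(1) < 0.10) {
        poss <- nat[1]; nat <- nat[-1]
      }
      if (length(ext) > 0 && runif(1) < 0.3) {
        pex <- ext; ext <- character(0)
      }
      list(extant = nat, possibly = poss, extinct = ext, possibly_extinct = pex)
    })
    all_native <- lapply(presence, function(p) {
      unique(c(p$extant, p$possibly, p$extinct, p$possibly_extinct))
    })
    introduced <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.25) {
        pool <- setdiff(world$country, all_native[[i]])
        sample(pool, min(length(pool), sample(1:3, 1)))
      } else character(0)
    })
    sp$home_realm <- home
    sp$native_extant <- lapply(presence, `[[`, "extant")
    sp$native_possibly_extant <- lapply(presence, `[[`, "possibly")
    sp$extinct_range <- lapply(presence, `[[`, "extinct")
    sp$possibly_extinct <- lapply(presence, `[[`, "possibly_extinct")
    sp$introduced <- introduced
    sp[sample.int(n), ]
  })
}

#' Generate a synonym / common-name key table for a species pool
#'
#' Emits the name-key table used by the harmonization stage: every accepted
#' scientific name plus a random number of synonyms and vernacular names,
#' each mapping to exactly one accepted name.
#'
#' @param species Species master from [simulate_species()].
#' @param config A [sim_config()] object.
#' @return A tibble with columns `key_string`, `key_type` (`scientific`,
#'   `synonym` or `common`), `language`, `accepted_name`.
#' @export
simulate_keys <- function(species, config) {
  validate_config(config)
  assert_columns(species, c("accepted_name", "genus"))
  with_stream(config$seed, "keys", {
    n <- nrow(species)
    sci <- tibble(key_string = species$accepted_name, key_type = "scientific",
                  language = "scientific", accepted_name = species$accepted_name)
    n_syn <- rpois(n, 1.2)
    syn <- tibble(
      key_string = paste(
        synth_genus(sample.int(3000L, sum(n_syn), replace = TRUE),
                    suffix = "ix"),
        rep(sub("^\\S+ ", "", species$accepted_name), n_syn)),
      key_type = "synonym", language = "scientific",
      accepted_name = rep(species$accepted_name, n_syn))
    n_com <- rpois(n, 0.8)
    adj <- c("greater", "lesser", "eastern", "western", "northern",
             "southern", "spotted", "banded", "crested", "dwarf", "giant",
             "golden", "ornate", "painted", "ringed")
    nouns <- c("boa", "gecko", "parrot", "finch", "macaque", "newt", "toad",
               "monitor", "viper", "lorikeet", "marmoset", "skink", "frog",
               "turtle", "civet")
    com <- tibble(
      key_string = paste(sample(adj, sum(n_com), TRUE),
                         sample(nouns, sum(n_com), TRUE),
                         synth_epithet(700000L + sample.int(600000L, sum(n_com)))),
      key_type = "common", language = "en",
      accepted_name = rep(species$accepted_name, n_com))
    keys <- bind_rows(sci, syn, com)
    keys$key_string <- tolower(keys$key_string)
    # a key must map to exactly one accepted name
    keys <- keys[!duplicated(keys$key_string), ]
    keys
  })
}

# deterministic latin-ish unique name builders (base-k syllable encoding);
# class ranges are disjoint and below 15^3 so codes never wrap, and
# synonym genera use a distinct suffix so they can never collide with an
# accepted name
synth_genus <- function(i, suffix = "us") {
  syl <- c("ba", "ca", "da", "fe", "gi", "lo", "mu", "ne", "po", "ra",
           "si", "tu", "ve", "xa", "zo")
  k <- length(syl)
  i <- i %% (k * k * k)
  s <- paste0(syl[(i %/% (k * k)) %% k + 1], syl[(i %/% k) %% k + 1],
              syl[i %% k + 1], suffix)
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

synth_epithet <- function(i) {
  syl <- c("bel", "cor", "del", "fen", "gal", "hol", "jun", "kel", "lim",
           "mor", "nid", "pel", "qui", "ros", "sul", "tam", "urn", "vex")
  k <- length(syl)
  paste0(syl[(i %/% (k * k)) %% k + 1], syl[(i %/% k) %% k + 1],
         syl[i %% k + 1], "a")
}

class_offset <- function(cl) {
  (match(cl, c("mammal", "bird", "reptile", "amphibian")) - 1L) * 800L
}
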