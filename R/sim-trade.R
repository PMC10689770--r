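#' Generate raw trade records from four overlapping sources
#'
#' Builds the synthetic raw trade tables for the four source dialects:
#' structured trade-report rows (`CITES`, `LEMIS`), zoo-inventory rows
#' (`ISIS`) and free-text online listings (`OTAPS`). Source membership is
#' arranged so that, after harmonization, the number of distinct species per
#' source equals `config$source_marginals` exactly, with co-membership
#' concentration controlled by `overlap_control`. Each species trades in
#' `1 + NB(size, mu)` countries, each drawn from outside its native range
#' with probability `p_alien_trade`. A configured fraction of extra records
#' violates the quality-control rules (duplicated lines, identical importer
#' and exporter, missing names, hybrid or genus-only names, non-live terms,
#' zoo rows for threatened species, unresolvable typos and key-free junk
#' listings); every planted violation is booked in a ledger so downstream
#' removals can be reconciled exactly.
#'
#' @param species Species master from [simulate_species()].
#' @param world Country table from [simulate_world()].
#' @param keys Key table from [simulate_keys()].
#' @param config A [sim_config()] object.
#' @return A tibble of raw records with columns `source`, `sci_name`,
#'   `listing_text`, `importer`, `exporter`, `country`, `year`, `term`.
#'   Attribute `ledger` holds: `planted` (counts of planted rule
#'   violations), `truth_pairs` (species x country with the planted
#'   alien/native label), `membership` (species x source) and `breadth`
#'   (per-species planned number of trading countries).
#' @export
simulate_trade <- function(species, world, keys, config) {
  validate_config(config)
  assert_columns(species, c("accepted_name", "iucn_category", "genus"))
  n_sp <- nrow(species)
  native_sets <- native_range_sets(species)
  threatened <- species$iucn_category %in% c("VU", "EN", "CR")
  if (config$source_marginals[["ISIS"]] > sum(!threatened)) {
    abort("ISIS marginal exceeds the non-threatened species pool.")
  }

  with_stream(config$seed, "trade", {
    membership <- draw_membership(n_sp, threatened, config)

    # trade countries per species, with the alien/native split planted
    rng_k <- 1L + rnbinom(n_sp, size = config$breadth$size,
                          mu = config$breadth$mu)
    rng_k <- pmin(rng_k, config$n_countries - 1L)
    countries <- world$country
    # importing-power weights: richer, larger, more trade-active countries
    # attract more alien-trade draws (shared across classes)
    ia <- config$import_attraction
    zs <- function(v) as.vector(scale(log(v)))
    attract <- exp(ia[["population"]] * zs(world$population) +
                     ia[["trade_value"]] * zs(world$trade_value) +
                     ia[["gdp_pc"]] * zs(world$gdp_pc))
    names(attract) <- countries
    pair_list <- vector("list", n_sp)
    for (i in seq_len(n_sp)) {
      k <- rng_k[i]
      nat_pool <- native_sets[[i]]
      n_alien <- rbinom(1, k, config$p_alien_trade)
      n_native <- min(k - n_alien, length(nat_pool))
      alien_pool <- setdiff(countries, nat_pool)
      n_alien <- min(n_alien, length(alien_pool))
      cc <- c(if (n_native > 0) sample(nat_pool, n_native),
              if (n_alien > 0) resample(alien_pool, n_alien,
                                        prob = attract[alien_pool]))
      if (length(cc) == 0) cc <- resample(alien_pool, 1)
      pair_list[[i]] <- tibble(
        sp = i, country = cc,
        label = ifelse(cc %in% nat_pool, "native", "alien"))
    }
    pairs <- bind_rows(pair_list)

    # distribute each (species, country) pair over the species' sources;
    # every source a species belongs to receives at least one pair, and a
    # small fraction of pairs is cross-listed in a second source
    src_of <- split(membership$source, membership$sp)
    rec_list <- vector("list", n_sp)
    pair_by_sp <- split(seq_len(nrow(pairs)), pairs$sp)
    for (i in seq_len(n_sp)) {
      srcs <- src_of[[as.character(i)]]
      pidx <- pair_by_sp[[as.character(i)]]
      assigned <- sample(srcs, length(pidx), replace = TRUE)
      out <- data.frame(pair = pidx, source = assigned)
      missing <- setdiff(srcs, assigned)
      if (length(missing) > 0) {
        out <- rbind(out, data.frame(
          pair = resample(pidx, length(missing), replace = TRUE),
          source = missing))
      }
      extra <- pidx[runif(length(pidx)) < 0.08 & length(srcs) > 1]
      if (length(extra) > 0) {
        cur <- assigned[match(extra, pidx)]
        alt <- vapply(cur, function(s) sample(setdiff(srcs, s), 1), "")
        out <- rbind(out, data.frame(pair = extra, source = alt))
      }
      rec_list[[i]] <- unique(out)
    }
    rec <- bind_rows(rec_list)
    rec$sp <- pairs$sp[rec$pair]
    rec$country <- pairs$country[rec$pair]

    base <- build_base_records(rec, species, keys, native_sets, world, config)
    planted <- plant_violations(base, species, keys, threatened, membership,
                                world, config)
    raw <- bind_rows(base, planted$rows)
    raw <- raw[sample.int(nrow(raw)), ]

    truth_pairs <- tibble(accepted_name = species$accepted_name[pairs$sp],
                          country = pairs$country, label = pairs$label)
    attr(raw, "ledger") <- list(
      planted = planted$counts,
      truth_pairs = truth_pairs,
      membership = tibble(accepted_name = species$accepted_name[membership$sp],
                          source = membership$source),
      breadth = tibble(accepted_name = species$accepted_name,
                       n_trade_countries = as.integer(table(
                         factor(pairs$sp, levels = seq_len(n_sp)))))
    )
    raw
  })
}

#' @rdname simulate_trade
#' @param trade A raw trade table produced by `simulate_trade()`.
#' @export
trade_ledger <- function(trade) {
  attr(trade, "ledger")
}

# membership counts per species over {1..4} sources, honoring the
# per-source totals and the unique-species share
draw_membership <- function(n_sp, threatened, config) {
  marg <- config$source_marginals
  sources <- names(marg)
  total <- sum(marg)
  n1 <- round(config$p_unique * n_sp)
  # keep the multi-source mean within [2, 4]
  repeat {
    c_multi <- n_sp - n1
    t_multi <- total - n1
    if (c_multi <= 0) { n1 <- n_sp - 1; next }
    mbar <- t_multi / c_multi
    if (mbar > 4) n1 <- n1 - 1
    else if (mbar < 2 && n1 < n_sp - 1 && mbar != 1) n1 <- n1 + 1
    else break
    if (n1 < 0) abort("source marginals inconsistent with species pool size.")
  }
  nm <- solve_membership_counts(c_multi, t_multi)
  w <- rgamma(n_sp, shape = config$overlap_control, rate = 1) + 1e-9
  remaining <- seq_len(n_sp)
  m <- rep(1L, n_sp)
  elig4 <- remaining[!threatened[remaining]]
  pick4 <- resample(elig4, nm[["4"]], prob = w[elig4])
  m[pick4] <- 4L
  remaining <- setdiff(remaining, pick4)
  pick3 <- resample(remaining, nm[["3"]], prob = w[remaining])
  m[pick3] <- 3L
  remaining <- setdiff(remaining, pick3)
  pick2 <- resample(remaining, nm[["2"]], prob = w[remaining])
  m[pick2] <- 2L

  cap <- marg
  order_sp <- order(-m, runif(n_sp))
  mem <- vector("list", n_sp)
  for (i in order_sp) {
    eligible <- if (threatened[i]) setdiff(sources, "ISIS") else sources
    allowed <- eligible[cap[eligible] > 0]
    if (length(allowed) == 0) allowed <- eligible  # overfill; repaired below
    take <- min(m[i], length(allowed))
    pick <- if (take == length(allowed)) allowed else
      sample(allowed, take, prob = pmax(cap[allowed], 0.5))
    cap[pick] <- cap[pick] - 1L
    mem[[i]] <- pick
  }
  ms <- tibble(sp = rep(seq_len(n_sp), lengths(mem)), source = unlist(mem))
  # repair pass: move memberships until per-source counts are exact
  for (iter in seq_len(10000)) {
    realized <- table(factor(ms$source, levels = sources))
    diff <- as.integer(realized) - as.integer(marg)
    if (all(diff == 0)) break
    over <- sources[which(diff > 0)[1]]
    under <- sources[which(diff < 0)[1]]
    in_over <- unique(ms$sp[ms$source == over])
    in_under <- unique(ms$sp[ms$source == under])
    cand <- setdiff(in_over, in_under)
    if (under == "ISIS") cand <- cand[!threatened[cand]]
    if (length(cand) == 0) abort("cannot balance source marginals; relax config.")
    s <- if (length(cand) == 1) cand else sample(cand, 1)
    ms$source[ms$sp == s & ms$source == over] <- under
    ms <- unique(ms)
  }
  ms
}

# counts over multi-source membership sizes {2,3,4} with given total
# species count and total membership count (truncated-geometric shape)
solve_membership_counts <- function(c_multi, t_multi) {
  mbar <- t_multi / c_multi
  f <- function(th) (2 + 3 * th + 4 * th^2) / (1 + th + th^2) - mbar
  th <- if (f(1e-9) >= 0) 1e-9 else if (f(1e6) <= 0) 1e6 else
    stats::uniroot(f, c(1e-9, 1e6))$root
  p <- c(1, th, th^2); p <- p / sum(p)
  nm <- floor(p * c_multi)
  nm[1] <- c_multi - nm[2] - nm[3]
  # exact repair on both totals
  repeat {
    gap <- t_multi - sum(nm * c(2, 3, 4))
    if (gap == 0) break
    if (gap > 0) {
      j <- if (nm[1] > 0) 1 else 2
      nm[j] <- nm[j] - 1; nm[j + 1] <- nm[j + 1] + 1
    } else {
      j <- if (nm[3] > 0) 3 else 2
      nm[j] <- nm[j] - 1; nm[j - 1] <- nm[j - 1] + 1
    }
  }
  setNames(as.list(nm), c("2", "3", "4"))
}

build_base_records <- function(rec, species, keys, native_sets, world, config) {
  n <- nrow(rec)
  nm <- species$accepted_name[rec$sp]
  syn_rate <- config$noise$synonym
  alt_keys <- keys[keys$key_type != "scientific", ]
  alt_by_sp <- split(alt_keys$key_string, alt_keys$accepted_name)
  use_syn <- runif(n) < syn_rate
  picked <- nm
  has_alt <- nm %in% names(alt_by_sp)
  idx <- which(use_syn & has_alt)
  if (length(idx) > 0) {
    picked[idx] <- vapply(nm[idx], function(a) {
      ks <- alt_by_sp[[a]]
      if (length(ks) == 1) ks else sample(ks, 1)
    }, "", USE.NAMES = FALSE)
  }

  exporter <- rep(NA_character_, n)
  structured <- rec$source %in% c("CITES", "LEMIS")
  if (any(structured)) {
    si <- which(structured)
    exporter[si] <- vapply(si, function(j) {
      pool <- setdiff(native_sets[[rec$sp[j]]], rec$country[j])
      if (length(pool) == 0) pool <- setdiff(world$country, rec$country[j])
      if (length(pool) == 1) pool else sample(pool, 1)
    }, "")
  }
  year <- integer(n)
  year[rec$source == "CITES"] <- sample(1975:2021, sum(rec$source == "CITES"), TRUE)
  year[rec$source == "LEMIS"] <- sample(1999:2020, sum(rec$source == "LEMIS"), TRUE)
  year[rec$source == "ISIS"] <- 2011L
  year[rec$source == "OTAPS"] <- sample(2015:2022, sum(rec$source == "OTAPS"), TRUE)

  listing <- rep(NA_character_, n)
  ot <- which(rec$source == "OTAPS")
  if (length(ot) > 0) listing[ot] <- listing_text(picked[ot])

  tibble(
    source = rec$source,
    sci_name = ifelse(rec$source == "OTAPS", NA_character_, picked),
    listing_text = listing,
    importer = ifelse(structured, rec$country, NA_character_),
    exporter = exporter,
    country = rec$country,
    year = year,
    term = ifelse(structured, "live", NA_character_)
  )
}

# free-text listing around a planted key; junk vocabulary is disjoint from
# every key family so a listing contains exactly the key it was built on
junk_words <- c("adult", "pair", "juvenile", "cb2023", "shipping",
                "nationwide", "healthy", "terrarium", "cage", "heating",
                "lamp", "substrate", "feeders", "delivery", "courier",
                "available", "in stock", "best offer", "pickup", "proven")

listing_text <- function(key) {
  n <- length(key)
  pre <- vapply(sample(1:3, n, TRUE), function(k)
    paste(sample(junk_words, k), collapse = " "), "")
  post <- vapply(sample(1:4, n, TRUE), function(k)
    paste(sample(junk_words, k), collapse = " "), "")
  price <- paste0("$", sample(10:900, n, TRUE))
  paste(pre, key, post, price)
}

# corrupt a name so that neither it nor any real key occurs in the result
corrupt_name <- function(x) {
  sub("[aeiou]", "q", x)
}

plant_violations <- function(base, species, keys, threatened, membership,
                             world, config) {
  qc <- config$qc
  rows <- list()
  counts <- c(duplicate = 0L, same_importer_exporter = 0L, missing_name = 0L,
              hybrid = 0L, nonlive = 0L, typo = 0L, junk = 0L,
              isis_threatened = 0L)
  n_base <- nrow(base)
  structured_idx <- which(base$source %in% c("CITES", "LEMIS"))
  named_idx <- which(base$source != "OTAPS")

  n_dup <- round(qc$duplicate * n_base)
  if (n_dup > 0) {
    rows$dup <- base[sample(n_base, n_dup, replace = TRUE), ]
    counts["duplicate"] <- n_dup
  }
  n_ie <- round(qc$same_importer_exporter * length(structured_idx))
  if (n_ie > 0) {
    r <- base[sample(structured_idx, n_ie), ]
    r$exporter <- r$importer
    rows$ie <- r
    counts["same_importer_exporter"] <- n_ie
  }
  n_miss <- round(qc$missing_name * length(named_idx))
  if (n_miss > 0) {
    r <- base[sample(named_idx, n_miss), ]
    r$sci_name <- NA_character_
    rows$miss <- r
    counts["missing_name"] <- n_miss
  }
  n_hyb <- round(qc$hybrid * length(named_idx))
  if (n_hyb > 0) {
    r <- base[sample(named_idx, n_hyb), ]
    forms <- c(" sp.", " spp.")
    g <- sample(unique(species$genus), n_hyb, replace = TRUE)
    hy <- runif(n_hyb) < 0.5
    r$sci_name <- ifelse(hy,
                         paste(g, "bellus ×", g, "alter"),
                         paste0(g, sample(forms, n_hyb, TRUE)))
    rows$hyb <- r
    counts["hybrid"] <- n_hyb
  }
  n_nl <- round(qc$nonlive * length(structured_idx))
  if (n_nl > 0) {
    r <- base[sample(structured_idx, n_nl), ]
    r$term <- sample(c("skins", "eggs", "trophies", "specimens"), n_nl, TRUE)
    rows$nl <- r
    counts["nonlive"] <- n_nl
  }
  n_typo <- round(config$noise$typo * n_base)
  if (n_typo > 0) {
    r <- base[sample(n_base, n_typo), ]
    named <- r$source != "OTAPS"
    r$sci_name[named] <- corrupt_name(r$sci_name[named])
    if (any(!named)) {
      r$listing_text[!named] <- listing_text(corrupt_name(
        tolower(sample(species$accepted_name, sum(!named), replace = TRUE))))
    }
    rows$typo <- r
    counts["typo"] <- n_typo
  }
  ot_idx <- which(base$source == "OTAPS")
  n_junk <- round(config$noise$junk * length(ot_idx))
  if (n_junk > 0) {
    r <- base[sample(ot_idx, n_junk, replace = TRUE), ]
    r$listing_text <- vapply(seq_len(n_junk), function(i)
      paste(paste(sample(junk_words, 5), collapse = " "),
            paste0("ref", i)), "")
    rows$junk <- r
    counts["junk"] <- n_junk
  }
  thr_sp <- which(threatened)
  n_isis <- round(qc$isis_threatened * sum(base$source == "ISIS"))
  if (n_isis > 0 && length(thr_sp) > 0) {
    pick <- resample(thr_sp, n_isis, replace = TRUE)
    rows$isis <- tibble(
      source = "ISIS",
      sci_name = species$accepted_name[pick],
      listing_text = NA_character_,
      importer = NA_character_, exporter = NA_character_,
      country = sample(world$country, n_isis, replace = TRUE),
      year = 2011L, term = NA_character_)
    counts["isis_threatened"] <- n_isis
  }
  list(rows = bind_rows(rows), counts = counts)
}

# native range as the union of the four native presence categories
native_range_sets <- function(species) {
  lapply(seq_len(nrow(species)), function(i) {
    unique(c(species$native_extant[[i]],
             species$native_possibly_extant[[i]],
             species$extinct_range[[i]],
             species$possibly_extinct[[i]]))
  })
}
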