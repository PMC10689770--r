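#' Build a length-sorted name-key index
#'
#' Lowercases all key strings and orders them ascending by character length,
#' breaking equal-length ties lexicographically. This reproduces the
#' sorted-lookup-array mechanism used to pull species names out of free
#' text: scanning the whole index and keeping the last hit returns the
#' longest key occurring in a text.
#'
#' @param keys A data frame with columns `key_string` and `accepted_name`
#'   (optionally `key_type`, `language`).
#' @return A tibble of class `colpress_key_index`, ordered as described.
#' @examples
#' idx <- build_key_index(data.frame(
#'   key_string = c("boa", "boa constrictor"),
#'   accepted_name = "Boa constrictor"))
#' idx$key_string
#' @export
build_key_index <- function(keys) {
  assert_columns(keys, c("key_string", "accepted_name"))
  if (nrow(keys) == 0) abort("key set is empty.")
  keys <- as_tibble(keys)
  keys$key_string <- tolower(keys$key_string)
  keys <- keys[!duplicated(keys[, c("key_string", "accepted_name")]), ]
  dup <- keys$key_string[duplicated(keys$key_string)]
  if (length(dup) > 0) {
    bad <- keys[keys$key_string %in% dup, c("key_string", "accepted_name")]
    abort(c("ambiguous keys map to multiple accepted names:",
            utils::capture.output(print(as.data.frame(bad)))))
  }
  keys <- keys[order(nchar(keys$key_string), keys$key_string), ]
  class(keys) <- c("colpress_key_index", class(keys))
  keys
}

#' Extract a species-name key from free text
#'
#' Case-insensitive substring search of every key in the index against each
#' text; among all keys occurring in a text, the one ordered last in the
#' index (the longest, ties broken lexicographically last) is returned,
#' mirroring lookup-over-sorted-array semantics. Matching is raw substring
#' search without word-boundary enforcement unless `word_boundary = TRUE`.
#'
#' @param text Character vector of free-text listings.
#' @param index A [build_key_index()] result.
#' @param word_boundary If `TRUE`, a key only matches when flanked by
#'   non-word characters or string edges.
#' @return Character vector: the matched key per text, `NA` where no key
#'   occurs.
#' @examples
#' idx <- build_key_index(data.frame(
#'   key_string = c("python", "burmese python"),
#'   accepted_name = c("Python bivittatus", "Python bivittatus")))
#' extract_name("Burmese python hatchling, ships nationwide", idx)
#' @export
extract_name <- function(text, index, word_boundary = FALSE) {
  stopifnot(inherits(index, "colpress_key_index"))
  low <- tolower(text)
  out <- rep(NA_character_, length(low))
  kk <- index$key_string
  # exact inverted prefilter: a key can only occur in a text if its first
  # three characters occur there, so candidate (text, key) pairs come from
  # a trigram index; keys shorter than 3 characters are tested everywhere
  lens <- nchar(low)
  reps <- pmax(lens - 2L, 0L)
  starts <- unlist(lapply(reps, seq_len))
  tri_tab <- tibble(
    text_id = rep(seq_along(low), reps),
    tok = substring(rep(low, reps), starts, starts + 2L))
  tri_tab <- tri_tab[!duplicated(tri_tab), ]
  key_tab <- tibble(key_id = seq_along(kk), tok = substr(kk, 1, 3))
  cand <- inner_join(tri_tab, key_tab, by = "tok",
                     relationship = "many-to-many")[, c("text_id", "key_id")]
  short <- which(nchar(kk) < 3)
  if (length(short) > 0) {
    cand <- bind_rows(cand, tidyr::expand_grid(text_id = seq_along(low),
                                               key_id = short))
  }
  cand <- cand[!duplicated(cand), ]
  if (nrow(cand) > 0) {
    hit <- vapply(seq_len(nrow(cand)), function(i) {
      key_occurs(kk[cand$key_id[i]], low[cand$text_id[i]], word_boundary)
    }, logical(1))
    cand <- cand[hit, ]
    if (nrow(cand) > 0) {
      best <- cand %>%
        group_by(.data$text_id) %>%
        summarise(key_id = max(.data$key_id), .groups = "drop")
      out[best$text_id] <- kk[best$key_id]
    }
  }
  out
}

key_occurs <- function(key, text, word_boundary) {
  if (word_boundary) {
    grepl(paste0("(^|[^a-z0-9])", escape_regex(key), "($|[^a-z0-9])"), text)
  } else {
    grepl(key, text, fixed = TRUE)
  }
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Resolve key strings to accepted names
#'
#' Exact (lowercased) lookup of each key against the key table. Unresolved
#' strings return `NA`; downstream stages exclude and count them.
#'
#' @param key_string Character vector of keys (or raw name strings).
#' @param keys Key table with `key_string` and `accepted_name`.
#' @return Character vector of accepted names, `NA` where unresolved.
#' @export
resolve_accepted <- function(key_string, keys) {
  assert_columns(keys, c("key_string", "accepted_name"))
  keys$accepted_name[match(tolower(key_string), tolower(keys$key_string))]
}

#' Clean raw trade records
#'
#' Applies the quality-control rules to the raw tables, in order: keep only
#' `term == "live"` rows for the structured dialects (`CITES`, `LEMIS`);
#' drop rows with no scientific name (structured and zoo dialects); drop
#' genus-only (`sp.`, `spp.`) and hybrid (`x`, `hybrid`) names; drop rows
#' whose importer equals their exporter; drop exactly duplicated lines.
#' Rows from unknown sources raise an error. Cleaning is idempotent and the
#' removal report reconciles: removals sum to rows in minus rows out.
#'
#' @param raw Raw trade tibble (see [simulate_trade()] for the schema).
#' @return The surviving rows, with a `report` attribute: a tibble of
#'   per-rule removal counts.
#' @export
clean_trade_records <- function(raw) {
  assert_columns(raw, c("source", "sci_name", "country"))
  known <- c("CITES", "LEMIS", "ISIS", "OTAPS")
  if (!all(raw$source %in% known)) {
    abort(sprintf("unknown source label(s): %s",
                  paste(setdiff(unique(raw$source), known), collapse = ", ")))
  }
  n0 <- nrow(raw)
  report <- list()

  structured <- raw$source %in% c("CITES", "LEMIS")
  drop <- structured & (is.na(raw$term) | raw$term != "live")
  report$non_live <- sum(drop)
  raw <- raw[!drop, ]

  named_src <- raw$source != "OTAPS"
  drop <- named_src & (is.na(raw$sci_name) | trimws(raw$sci_name) == "")
  report$missing_name <- sum(drop)
  raw <- raw[!drop, ]

  nm <- raw$sci_name
  bad_name <- !is.na(nm) &
    (grepl("\\bspp?\\.", nm) | grepl("×|\\bhybrid\\b", nm,
                                     ignore.case = TRUE))
  report$unidentified_or_hybrid <- sum(bad_name)
  raw <- raw[!bad_name, ]

  drop <- !is.na(raw$importer) & !is.na(raw$exporter) &
    raw$importer == raw$exporter
  report$same_importer_exporter <- sum(drop)
  raw <- raw[!drop, ]

  dup <- duplicated(raw)
  report$duplicated_line <- sum(dup)
  raw <- raw[!dup, ]

  rep_tbl <- tibble(rule = names(report),
                    removed = unlist(report, use.names = FALSE))
  stopifnot(sum(rep_tbl$removed) == n0 - nrow(raw))
  attr(raw, "report") <- rep_tbl
  raw
}

#' Drop zoo-inventory records of threatened species
#'
#' Zoo holdings of threatened species (IUCN categories VU, EN, CR) are
#' assumed to serve conservation rather than trade, so their zoo-source
#' rows are removed. Rows for the same species from other sources are left
#' untouched.
#'
#' @param records Records with `source` and `accepted_name` columns.
#' @param species Species master with `accepted_name` and `iucn_category`.
#' @return Filtered records; attribute `n_excluded` carries the count.
#' @export
exclude_isis_threatened <- function(records, species) {
  assert_columns(records, c("source", "accepted_name"))
  assert_columns(species, c("accepted_name", "iucn_category"))
  cat_of <- species$iucn_category[match(records$accepted_name,
                                        species$accepted_name)]
  drop <- records$source == "ISIS" & !is.na(cat_of) &
    cat_of %in% c("VU", "EN", "CR")
  out <- records[!drop, ]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Harmonize raw trade records end to end
#'
#' Runs the full record-preparation pipeline: quality-control cleaning,
#' name extraction from free-text listings via the key index, resolution of
#' all names to accepted taxonomy, exclusion of unresolved rows,
#' deduplication to distinct (species, country, source) observations, and
#' removal of zoo-source rows for threatened species.
#'
#' @param raw Raw trade tibble.
#' @param keys Name-key table.
#' @param species Species master (for the threatened-species exclusion).
#' @param word_boundary Passed to [extract_name()].
#' @return A tibble of clean records (`source`, `accepted_name`, `country`,
#'   `year`) with a `report` attribute: per-rule removal counts including
#'   `unresolved_name`, `isis_threatened` and `collapsed_duplicate_obs`.
#' @examples
#' cfg <- sim_config(scale = 0.01, n_countries = 25, seed = 4)
#' world <- simulate_world(cfg)
#' sp <- simulate_species(world, cfg)
#' keys <- simulate_keys(sp, cfg)
#' raw <- simulate_trade(sp, world, keys, cfg)
#' clean <- harmonize_trade(raw, keys, sp)
#' attr(clean, "report")
#' @export
harmonize_trade <- function(raw, keys, species, word_boundary = FALSE) {
  cleaned <- clean_trade_records(raw)
  report <- attr(cleaned, "report")

  idx <- build_key_index(keys)
  name_in <- cleaned$sci_name
  ot <- which(cleaned$source == "OTAPS")
  if (length(ot) > 0) {
    name_in[ot] <- extract_name(cleaned$listing_text[ot], idx,
                                word_boundary = word_boundary)
  }
  accepted <- resolve_accepted(name_in, idx)
  unresolved <- is.na(accepted)
  if (any(unresolved)) {
    inform(sprintf("%d record(s) with unresolved names excluded.",
                   sum(unresolved)))
  }
  out <- tibble(source = cleaned$source,
                accepted_name = accepted,
                country = cleaned$country,
                year = cleaned$year)[!unresolved, ]

  dup <- duplicated(out[, c("source", "accepted_name", "country")])
  n_dup_obs <- sum(dup)
  out <- out[!dup, ]

  out <- exclude_isis_threatened(out, species)
  n_isis <- attr(out, "n_excluded")

  report <- bind_rows(report,
                      tibble(rule = c("unresolved_name",
                                      "collapsed_duplicate_obs",
                                      "isis_threatened"),
                             removed = c(sum(unresolved), n_dup_obs, n_isis)))
  attr(out, "report") <- report
  attr(out, "n_excluded") <- NULL
  out
}
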