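#' Run the full synthetic-world analysis pipeline
#'
#' Executes the stages end to end: simulate (world, species, keys, trade),
#' harmonize, classify, establish, infer and flows, collecting every
#' artifact plus a run manifest with per-stage row counts. Any stage's
#' inputs can be supplied through `inputs` to skip its simulation, and
#' `stages` restricts how far the pipeline runs. Deterministic for a fixed
#' config (the config carries the seed).
#'
#' @param config A [sim_config()] object.
#' @param stages Character vector of stages to run, a prefix of
#'   `c("simulate", "harmonize", "classify", "establish", "infer",
#'   "flows")`. Later stages require earlier artifacts.
#' @param inputs Optional named list of precomputed artifacts (`world`,
#'   `species`, `keys`, `raw_trade`, `clean`, `classified`,
#'   `establishment`) used instead of generating them.
#' @return A list of class `colpress_run` with the artifacts, the
#'   summaries, and `manifest`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "harmonize", "classify",
                                    "establish", "infer", "flows"),
                         inputs = list()) {
  validate_config(config)
  all_stages <- c("simulate", "harmonize", "classify", "establish",
                  "infer", "flows")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  manifest <- list()
  note <- function(stage, n_in, n_out) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, rows_in = n_in, rows_out = n_out)
  }
  art <- list(config = config)

  if ("simulate" %in% stages) {
    art$world <- inputs$world %||% simulate_world(config)
    art$species <- inputs$species %||% simulate_species(art$world, config)
    art$keys <- inputs$keys %||% simulate_keys(art$species, config)
    art$raw_trade <- inputs$raw_trade %||%
      simulate_trade(art$species, art$world, art$keys, config)
    note("simulate", 0L, nrow(art$raw_trade))
  } else {
    art$world <- inputs$world
    art$species <- inputs$species
    art$keys <- inputs$keys
    art$raw_trade <- inputs$raw_trade
  }

  if ("harmonize" %in% stages) {
    if (is.null(art$raw_trade) || is.null(art$keys)) {
      abort("harmonize needs `raw_trade` and `keys` artifacts.")
    }
    art$clean <- inputs$clean %||%
      harmonize_trade(art$raw_trade, art$keys, art$species)
    note("harmonize", nrow(art$raw_trade), nrow(art$clean))
  }

  if ("classify" %in% stages) {
    art$classified <- inputs$classified %||%
      classify_records(art$clean, art$species)
    art$status <- species_alien_status(art$classified)
    src_sets <- lapply(split(art$classified$accepted_name,
                             art$classified$source), unique)
    art$venn <- venn_counts(src_sets[c("CITES", "LEMIS", "ISIS", "OTAPS")])
    note("classify", nrow(art$clean), nrow(art$classified))
  }

  if ("establish" %in% stages) {
    art$establishment <- inputs$establishment %||%
      simulate_establishment(art$classified, art$species, art$world, config)
    est_names <- unique(art$establishment$records$accepted_name)
    alien_sp <- art$status$accepted_name[art$status$alien_anywhere]
    art$match <- match_established(est_names, alien_sp)
    art$summary <- country_richness(art$classified, art$species, art$world,
                                    art$establishment$records)
    art$breadth <- trade_breadth(art$classified, art$world, art$species,
                                 established = est_names)
    art$breadth_summary <- breadth_summary(art$breadth)
    art$shares <- share_metrics(
      n_traded = n_distinct(art$classified$accepted_name),
      n_extant = config$n_extant,
      n_alien = length(alien_sp),
      n_established_traded = art$match$n_matched,
      n_established_total = art$match$n_established,
      n_native_only = sum(art$status$native_only),
      n_both = sum(art$status$both_alien_and_native))
    note("establish", nrow(art$classified),
         nrow(art$establishment$records))
  }

  if ("infer" %in% stages) {
    classes <- names(config$n_species_per_class)
    art$inference <- lapply(setNames(classes, classes), function(cl) {
      establishment_inference(art$summary[art$summary$class == cl, ])
    })
    breadth_alien <- art$breadth[art$breadth$accepted_name %in%
                                   art$status$accepted_name[
                                     art$status$alien_anywhere], ]
    fam <- art$species$family[match(breadth_alien$accepted_name,
                                    art$species$accepted_name)]
    art$glmm <- fit_logistic_mixed(breadth_alien$established,
                                   breadth_alien$n_trade_countries, fam)
    tot <- art$summary[art$summary$class == "total", ]
    art$paired <- paired_compare(tot$alien_richness, tot$native_richness)
    art$correlation <- cross_taxa_correlation(art$summary)
    note("infer", nrow(art$summary), length(classes))
  }

  if ("flows" %in% stages) {
    region_map <- art$world[, c("country", "region")]
    art$flow_all <- flow_matrix(art$classified, art$species, region_map,
                                filter = "all",
                                regions = config$region_names)
    est_alien <- art$match$established_by_trade
    art$flow_established <- flow_matrix(art$classified, art$species,
                                        region_map, filter = "established",
                                        established = est_alien,
                                        regions = config$region_names)
    note("flows", nrow(art$classified), sum(art$flow_all))
  }

  art$manifest <- bind_rows(manifest) %>%
    mutate(config_hash = config_hash(config), seed = config$seed,
           version = as.character(utils::packageVersion("colpress")))
  class(art) <- "colpress_run"
  art
}

config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' @export
print.colpress_run <- function(x, ...) {
  cat("<colpress_run>\n")
  print(as.data.frame(x$manifest))
  invisible(x)
}

#' Validate pipeline artifacts
#'
#' Schema, referential-integrity and invariant checks over a
#' [run_pipeline()] result: traded species must exist in the species
#' master, record countries in the country table, richness counts must be
#' non-negative, native and introduced ranges disjoint, and the Venn
#' regions must partition the union.
#'
#' @param run A `colpress_run` (or a compatible artifact list).
#' @return A tibble of violations (`check`, `detail`); zero rows on a
#'   clean run.
#' @export
validate_tables <- function(run) {
  v <- list()
  add <- function(check, detail) {
    v[[length(v) + 1]] <<- tibble(check = check, detail = detail)
  }
  if (!is.null(run$clean) && !is.null(run$species)) {
    orphans <- setdiff(unique(run$clean$accepted_name),
                       run$species$accepted_name)
    for (o in orphans) add("species_in_master", o)
  }
  if (!is.null(run$clean) && !is.null(run$world)) {
    orphans <- setdiff(unique(run$clean$country), run$world$country)
    for (o in orphans) add("country_in_world", o)
  }
  if (!is.null(run$summary)) {
    for (col in c("alien_richness", "native_richness",
                  "establishment_richness")) {
      n_bad <- sum(run$summary[[col]] < 0)
      if (n_bad > 0) add("non_negative_richness",
                         sprintf("%s: %d negative", col, n_bad))
    }
  }
  if (!is.null(run$species) && "introduced" %in% names(run$species)) {
    nat <- native_range_sets(run$species)
    bad <- vapply(seq_len(nrow(run$species)), function(i)
      length(intersect(nat[[i]], run$species$introduced[[i]])) > 0, TRUE)
    for (nm in run$species$accepted_name[bad]) {
      add("native_introduced_disjoint", nm)
    }
  }
  if (!is.null(run$venn)) {
    if (sum(run$venn$regions$n) != run$venn$union_size) {
      add("venn_partition", sprintf("regions sum %d != union %d",
                                    sum(run$venn$regions$n),
                                    run$venn$union_size))
    }
  }
  if (length(v) == 0) {
    tibble(check = character(0), detail = character(0))
  } else {
    bind_rows(v)
  }
}

#' Write pipeline artifacts as CSV
#'
#' Writes the tabular artifacts of a run to a directory as UTF-8 CSV with
#' header rows, plus the manifest and the truth ledger (YAML).
#'
#' @param run A `colpress_run`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- function(df) {
    df[vapply(df, function(c) !is.list(c), TRUE)]
  }
  tables <- list(world = run$world, species = flat_species(run$species),
                 keys = run$keys, clean_trade = run$clean,
                 classified = run$classified,
                 country_summary = run$summary,
                 breadth = run$breadth, manifest = run$manifest)
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      utils::write.csv(flat(tables[[nm]]),
                       file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE, fileEncoding = "UTF-8")
    }
  }
  if (!is.null(run$establishment)) {
    utils::write.csv(run$establishment$records,
                     file.path(dir, "establishment.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    write_truth_ledger(run$establishment$truth,
                       file.path(dir, "truth_ledger.yaml"))
  }
  if (!is.null(run$flow_all)) {
    utils::write.csv(as.data.frame(unclass(run$flow_all)),
                     file.path(dir, "flow_all.csv"), row.names = TRUE,
                     fileEncoding = "UTF-8")
    utils::write.csv(export_chord(run$flow_all),
                     file.path(dir, "flow_all_edges.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

# species master with the country-set list-columns serialized as
# semicolon-joined strings
flat_species <- function(species) {
  if (is.null(species)) return(NULL)
  out <- species
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(out[[col]], paste, "", collapse = ";")
    }
  }
  out
}
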