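#' Validate a country-to-region assignment
#'
#' Checks that every analysis country maps to one of the eight configured
#' economic regions. Countries missing from the map are excluded with a
#' warning; a region label outside the configured set is an error.
#'
#' @param countries Character vector of country ids in the analysis.
#' @param region_map Data frame with columns `country` and `region`.
#' @param regions The allowed region names (default the 8 world economic
#'   regions of [sim_config()]).
#' @return A tibble `country`, `region` covering the mapped countries;
#'   attribute `n_unmapped` counts exclusions.
#' @export
assign_regions <- function(countries, region_map,
                           regions = sim_config()$region_names) {
  assert_columns(region_map, c("country", "region"))
  bad <- setdiff(unique(region_map$region), regions)
  if (length(bad) > 0) {
    abort(sprintf("region label(s) outside the configured set: %s",
                  paste(bad, collapse = ", ")))
  }
  out <- tibble(country = unique(countries))
  out$region <- region_map$region[match(out$country, region_map$country)]
  unmapped <- sum(is.na(out$region))
  if (unmapped > 0) {
    warn(sprintf("%d countr%s without a region mapping excluded.",
                 unmapped, if (unmapped == 1) "y" else "ies"))
  }
  out <- out[!is.na(out$region), ]
  attr(out, "n_unmapped") <- unmapped
  out
}

#' Interregional species-flow matrix
#'
#' Counts one flow per distinct (species, donor region, recipient region)
#' triple, where the species is native in at least one country of the
#' donor region and traded as an alien in at least one country of the
#' recipient region. A species native in two regions and alien-traded in
#' three therefore contributes six triples; the diagonal holds
#' intraregional exchange (native and alien-traded in different countries
#' of the same region). With `filter = "established"` only
#' established-by-trade species are counted.
#'
#' @param classified Classified records ([classify_records()]).
#' @param species Species master (for native ranges).
#' @param region_map Data frame `country`, `region`.
#' @param filter `"all"` (every traded alien) or `"established"`.
#' @param established Character vector of established species (required
#'   when `filter = "established"`).
#' @param regions Allowed region names.
#' @return An 8x8 integer matrix of class `colpress_flow` (rows = donor,
#'   columns = recipient) with a `filter` attribute.
#' @export
flow_matrix <- function(classified, species, region_map,
                        filter = c("all", "established"),
                        established = NULL,
                        regions = sim_config()$region_names) {
  filter <- match.arg(filter)
  assert_columns(classified, c("accepted_name", "country", "label"))
  alien <- classified[classified$label == "alien", ]
  if (filter == "established") {
    if (is.null(established)) {
      abort("`established` must be supplied when filter = \"established\".")
    }
    alien <- alien[alien$accepted_name %in% established, ]
  }
  reg_of <- setNames(region_map$region, region_map$country)
  bad <- setdiff(unique(region_map$region), regions)
  if (length(bad) > 0) {
    abort(sprintf("region label(s) outside the configured set: %s",
                  paste(bad, collapse = ", ")))
  }

  # recipient side: distinct (species, region) with an alien-trade record
  rec <- alien
  rec$region <- unname(reg_of[rec$country])
  rec <- rec[!is.na(rec$region), c("accepted_name", "region")]
  rec <- rec[!duplicated(rec), ]

  # donor side: distinct (species, region) over native-range countries
  sp <- native_range(species)
  don <- tibble(
    accepted_name = rep(sp$accepted_name, lengths(sp$native_countries)),
    country = unlist(sp$native_countries))
  don <- don[don$accepted_name %in% rec$accepted_name, ]
  don$region <- unname(reg_of[don$country])
  don <- don[!is.na(don$region), c("accepted_name", "region")]
  don <- don[!duplicated(don), ]

  triples <- inner_join(don, rec, by = "accepted_name",
                        suffix = c("_donor", "_recipient"),
                        relationship = "many-to-many")
  m <- matrix(0L, length(regions), length(regions),
              dimnames = list(donor = regions, recipient = regions))
  if (nrow(triples) > 0) {
    tab <- table(factor(triples$region_donor, levels = regions),
                 factor(triples$region_recipient, levels = regions))
    m[] <- as.integer(tab)
  }
  structure(m, filter = filter, class = c("colpress_flow", "matrix", "array"))
}

#' Donor and recipient totals of a flow matrix
#'
#' @param flow A [flow_matrix()] result.
#' @return A list `donor` (row sums), `recipient` (column sums),
#'   `grand_total`.
#' @export
region_totals <- function(flow) {
  stopifnot(is.matrix(flow))
  list(donor = rowSums(flow), recipient = colSums(flow),
       grand_total = sum(flow))
}

#' Long-format edge table of a flow matrix
#'
#' One row per non-zero entry, suitable for chord-diagram rendering;
#' [chord_to_matrix()] round-trips it back.
#'
#' @param flow A [flow_matrix()] result.
#' @return A tibble `donor`, `recipient`, `count`.
#' @export
export_chord <- function(flow) {
  stopifnot(is.matrix(flow))
  idx <- which(flow > 0, arr.ind = TRUE)
  out <- tibble(donor = rownames(flow)[idx[, 1]],
                recipient = colnames(flow)[idx[, 2]],
                count = as.integer(flow[idx]))
  out[order(out$donor, out$recipient), ]
}

#' @rdname export_chord
#' @param edges An edge table from `export_chord()`.
#' @param regions Region names defining the matrix order.
#' @export
chord_to_matrix <- function(edges, regions = sim_config()$region_names) {
  assert_columns(edges, c("donor", "recipient", "count"))
  m <- matrix(0L, length(regions), length(regions),
              dimnames = list(donor = regions, recipient = regions))
  if (nrow(edges) > 0) {
    m[cbind(match(edges$donor, regions),
            match(edges$recipient, regions))] <- as.integer(edges$count)
  }
  structure(m, class = c("colpress_flow", "matrix", "array"))
}

#' @export
print.colpress_flow <- function(x, ...) {
  cat(sprintf("<colpress_flow> %s, grand total %d\n",
              attr(x, "filter") %||% "flow", sum(x)))
  print(unclass(x))
  invisible(x)
}
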