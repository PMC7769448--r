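# Matching resolved taxa against the barcode store and classifying each
# species by barcode availability and geographic provenance.

#' Match one taxon's name sub-list against the store
#'
#' @param taxon one row of the taxa tibble from [resolve_names()] (or any list
#'   with a `search_list` element).
#' @param store record-store tibble.
#' @return character vector of matched `record_id`s (union over the valid name
#'   and all synonyms; label comparison is case-insensitive after
#'   normalization).
#' @export
match_taxon <- function(taxon, store) {
  targets <- norm_species(unlist(taxon$search_list %||% taxon[["search_list"]]))
  store$record_id[norm_species(store$species_label) %in% targets]
}

# record_id -> taxon assignment for all taxa at once; returns a tibble
# (record_id, valid_name). Records claimed by two taxa (possible with an
# inconsistent synonym table) appear once per claimant and are surfaced in
# the collision report rather than silently tie-broken.
match_all <- function(taxa, store) {
  if (nrow(taxa) == 0 || nrow(store) == 0) {
    return(structure(tibble(record_id = character(), valid_name = character()),
                     collisions = tibble(record_id = character(),
                                         valid_names = character())))
  }
  lookup <- tibble(
    valid_name = rep(taxa$valid_name, lengths(taxa$search_list)),
    label_key = norm_species(unlist(taxa$search_list))
  )
  hits <- tibble(record_id = store$record_id,
                 label_key = norm_species(store$species_label)) |>
    dplyr::inner_join(lookup, by = "label_key",
                      relationship = "many-to-many") |>
    select("record_id", "valid_name") |>
    distinct()
  coll <- hits |>
    group_by(.data$record_id) |>
    summarise(n_taxa = dplyr::n(),
              valid_names = paste(sort(.data$valid_name), collapse = ";"),
              .groups = "drop") |>
    filter(.data$n_taxa > 1) |>
    select("record_id", "valid_names")
  attr(hits, "collisions") <- coll
  hits
}

#' Records claimed by more than one taxon
#'
#' @param summaries result of [classify_species()].
#' @return tibble `record_id`, `valid_names` (semicolon-joined claimants).
#' @export
match_collisions <- function(summaries) {
  attr(summaries, "collisions") %||%
    tibble(record_id = character(), valid_names = character())
}

#' Classify species by barcode availability and provenance
#'
#' For every resolved taxon: `availability` is `"none"` (no matching record),
#' `"private_only"` (matches but none public) or `"public"` (at least one
#' public record). `distribution` is assessed on public records only (a
#' private in-region record does not make a species "inside"; set
#' `public_only_distribution = FALSE` to relax): `"inside"` iff at least one
#' qualifying record is in-region, `"outside"` otherwise, `"not_applicable"`
#' when availability is not public.
#'
#' @param taxa taxa tibble from [resolve_names()].
#' @param store record-store tibble.
#' @param region a [region_spec()].
#' @param public_only_distribution assess provenance on public records only
#'   (default) or on all matched records.
#' @return a tibble with one row per taxon: `valid_name`, `taxon_group`,
#'   `n_records`, `n_public`, `n_private`, `availability`, `distribution`,
#'   `matched_record_ids` (list). Collision report attached (see
#'   [match_collisions()]). The result is invariant to store row order.
#' @export
classify_species <- function(taxa, store, region,
                             public_only_distribution = TRUE) {
  hits <- match_all(taxa, store)
  in_reg <- stats::setNames(record_in_region(store, region), store$record_id)
  is_pub <- stats::setNames(store$visibility == "public", store$record_id)

  per_taxon <- hits |>
    group_by(.data$valid_name) |>
    summarise(matched_record_ids = list(sort(.data$record_id)),
              .groups = "drop")

  out <- taxa |>
    select("valid_name", "taxon_group") |>
    left_join(per_taxon, by = "valid_name")
  out$matched_record_ids <- purrr::map(out$matched_record_ids,
                                       function(x) x %||% character(0))
  out$n_records <- lengths(out$matched_record_ids)
  out$n_public <- vapply(out$matched_record_ids,
                         function(ids) sum(is_pub[ids]), integer(1))
  out$n_private <- out$n_records - out$n_public
  out$availability <- ifelse(out$n_records == 0, "none",
                             ifelse(out$n_public >= 1, "public", "private_only"))
  out$distribution <- vapply(seq_len(nrow(out)), function(i) {
    if (out$availability[i] != "public") return("not_applicable")
    ids <- out$matched_record_ids[[i]]
    if (public_only_distribution) ids <- ids[is_pub[ids]]
    if (any(in_reg[ids])) "inside" else "outside"
  }, character(1))
  out <- arrange(out, .data$valid_name)
  attr(out, "collisions") <- attr(hits, "collisions")
  out
}

#' Per-species match table for export
#'
#' The machine twin of an availability/distribution alluvial: one row per
#' species with its record counts and classes.
#'
#' @param summaries result of [classify_species()].
#' @return tibble without list-columns, ready for [write_report()].
#' @export
match_summary_table <- function(summaries) {
  summaries |>
    select("valid_name", "taxon_group", "n_records", "n_public", "n_private",
           "availability", "distribution")
}
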