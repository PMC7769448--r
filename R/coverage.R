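# Coverage tables, exclusive country-combination shared-species counts and
# per-country group compositions.

#' Coverage rows from per-group counts
#'
#' The elementary coverage computation: given, per group, the number of
#' checklist species (`n_obis`), the number with at least one barcode record
#' of any visibility (`n_bold`) and the number with a public in-region barcode
#' (`n_sep`), compute the two percentages relative to `n_obis` and append a
#' totals row whose percentages are recomputed from the summed counts (never
#' by summing percentages). Percentages are kept exact here; rounding happens
#' at serialization ([write_report()]) or via `round_half_away()`.
#'
#' @param counts tibble with columns `group`, `n_obis`, `n_bold`, `n_sep`.
#' @param total_label label for the totals row; `NULL` suppresses it.
#' @return tibble `group`, `n_obis`, `n_bold`, `pct_bold`, `n_sep`, `pct_sep`.
#' @export
coverage_from_counts <- function(counts, total_label = "Total") {
  counts <- as_tibble(counts)
  require_cols(counts, c("group", "n_obis", "n_bold", "n_sep"), "coverage counts")
  bad <- counts$n_sep > counts$n_bold | counts$n_bold > counts$n_obis
  if (any(bad)) {
    abort(paste0("coverage invariant n_sep <= n_bold <= n_obis violated for: ",
                 paste(counts$group[bad], collapse = ", ")))
  }
  if (!is.null(total_label)) {
    counts <- bind_rows(counts, tibble(
      group = total_label,
      n_obis = sum(counts$n_obis),
      n_bold = sum(counts$n_bold),
      n_sep = sum(counts$n_sep)))
  }
  counts$pct_bold <- ifelse(counts$n_obis > 0, 100 * counts$n_bold / counts$n_obis, 0)
  counts$pct_sep <- ifelse(counts$n_obis > 0, 100 * counts$n_sep / counts$n_obis, 0)
  counts[c("group", "n_obis", "n_bold", "pct_bold", "n_sep", "pct_sep")]
}

#' Coverage table from match summaries
#'
#' Per taxon group: species on the checklist, species with at least one
#' barcode record (public or private), and species with a public barcode
#' collected in-region.
#'
#' @param summaries result of [classify_species()].
#' @param grouping optional named character vector `valid_name -> group`
#'   overriding the `taxon_group` column; species without a group fall into
#'   `"unassigned"` (with a warning).
#' @inheritParams coverage_from_counts
#' @return coverage tibble as in [coverage_from_counts()], one row per group
#'   plus the totals row.
#' @export
coverage_table <- function(summaries, grouping = NULL, total_label = "Total") {
  grp <- summaries$taxon_group
  if (!is.null(grouping)) {
    grp <- unname(grouping[summaries$valid_name])
  }
  if (any(is.na(grp))) {
    warn(paste0(sum(is.na(grp)), " species without a taxon group assigned to 'unassigned'"))
    grp[is.na(grp)] <- "unassigned"
  }
  counts <- tibble(group = grp,
                   bold = summaries$availability %in% c("private_only", "public"),
                   sep = summaries$availability == "public" &
                     summaries$distribution == "inside") |>
    group_by(.data$group) |>
    summarise(n_obis = dplyr::n(), n_bold = sum(.data$bold),
              n_sep = sum(.data$sep), .groups = "drop") |>
    arrange(.data$group)
  coverage_from_counts(counts, total_label = total_label)
}

#' Exclusive shared-species counts over country combinations
#'
#' For k countries, counts species in each of the 2^k - 1 non-empty country
#' subsets under exclusive-membership semantics: a species reported from
#' exactly countries {A, B} counts once, in the {A, B} bucket, and in no
#' other. Subset counts therefore sum to the number of distinct species in
#' the dataset.
#'
#' @param country_sets named list: country -> character vector of species.
#' @return tibble `countries` (plus-joined, member order as given),
#'   `n_countries`, `n_species`, one row per non-empty subset, sorted by
#'   subset size then lexicographically.
#' @export
shared_species <- function(country_sets) {
  k <- length(country_sets)
  stopifnot(k >= 1)
  countries <- names(country_sets)
  if (is.null(countries) || any(countries == "")) {
    abort("country_sets must be a named list")
  }
  species <- sort(unique(unlist(country_sets, use.names = FALSE)))
  membership <- vapply(country_sets, function(s) species %in% s,
                       logical(length(species)))
  if (length(species) == 1) membership <- matrix(membership, nrow = 1)
  subsets <- purrr::map(seq_len(2^k - 1), function(m) {
    sort(countries[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  })
  key_of <- function(memb_row) paste(sort(countries[memb_row]), collapse = "+")
  sp_key <- apply(membership, 1, key_of)
  counts <- table(sp_key)
  out <- tibble(
    countries = vapply(subsets, paste, character(1), collapse = "+"),
    n_countries = lengths(subsets)
  )
  out$n_species <- as.integer(ifelse(is.na(counts[out$countries]), 0,
                                     counts[out$countries]))
  arrange(out, .data$n_countries, .data$countries)
}

#' Shared-species counts for the three standard datasets
#'
#' Convenience wrapper computing [shared_species()] for (1) all checklist
#' species, (2) species with any barcode record, (3) species with a public
#' in-region barcode.
#'
#' @param summaries result of [classify_species()].
#' @param species_countries tibble `valid_name`, `country`: which countries
#'   report each species (from the checklist).
#' @return tibble with a leading `dataset` column
#'   (`obis_all`/`barcoded`/`barcoded_sep`) stacked over the per-subset rows.
#' @export
shared_species_datasets <- function(summaries, species_countries) {
  countries <- sort(unique(species_countries$country))
  if (length(countries) == 0) {
    return(tibble(dataset = character(), countries = character(),
                  n_countries = integer(), n_species = integer()))
  }
  sets_for <- function(keep_names) {
    sub <- species_countries[species_countries$valid_name %in% keep_names, ]
    lapply(stats::setNames(countries, countries), function(cty)
      unique(sub$valid_name[sub$country == cty]))
  }
  datasets <- list(
    obis_all = summaries$valid_name,
    barcoded = summaries$valid_name[summaries$availability != "none"],
    barcoded_sep = summaries$valid_name[summaries$availability == "public" &
                                          summaries$distribution == "inside"]
  )
  purrr::imap_dfr(datasets, function(names_kept, ds) {
    res <- shared_species(sets_for(names_kept))
    res$dataset <- ds
    res[c("dataset", "countries", "n_countries", "n_species")]
  })
}

#' Per-country taxon-group composition
#'
#' Fraction of each country's species per taxon group; exact fractions (they
#' sum to 1 within numerical precision), rounded only at serialization.
#'
#' @param species_countries_groups tibble `valid_name`, `country`,
#'   `taxon_group` (one row per species-country pair).
#' @return tibble `country`, `taxon_group`, `n_species`, `prop`.
#' @export
group_composition <- function(species_countries_groups) {
  species_countries_groups |>
    distinct(.data$valid_name, .data$country, .data$taxon_group) |>
    count(.data$country, .data$taxon_group, name = "n_species") |>
    group_by(.data$country) |>
    mutate(prop = .data$n_species / sum(.data$n_species)) |>
    ungroup() |>
    arrange(.data$country, .data$taxon_group)
}
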