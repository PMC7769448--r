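# Species-level name filtering and synonym-aware resolution.

QUALIFIER_EPITHETS <- c("sp", "spp", "cf", "aff", "nov", "indet", "gen", "var")

#' Is a name a clean species-level binomial?
#'
#' A name passes iff it is exactly two tokens: a capitalized genus and a
#' lowercase epithet (internal hyphen allowed), with no open-nomenclature
#' qualifiers (`sp.`, `spp.`, `cf.`, `aff.` ...), hybrid signs, rank labels or
#' author/year strings. Author strings are not stripped: `"Engraulis ringens
#' Jenyns, 1842"` fails (use the `clean` hook of [filter_species_level()] to
#' pre-process if your checklist carries authorities).
#'
#' @param raw_name character vector of names.
#' @return logical vector.
#' @examples
#' is_binomial(c("Engraulis ringens", "Engraulis sp.", "Engraulis"))
#' @export
is_binomial <- function(raw_name) {
  x <- stringr::str_squish(stringi::stri_trans_nfc(as.character(raw_name)))
  shape_ok <- stringr::str_detect(
    x, "^[A-Z][a-z]+ [a-z]+(-[a-z]+)?$") & !is.na(x)
  epithet <- ifelse(shape_ok, stringr::str_split_i(x, " ", 2), NA_character_)
  shape_ok & !(epithet %in% QUALIFIER_EPITHETS)
}

#' Split a checklist into species-level and rejected entries
#'
#' @param entries checklist tibble ([read_checklist()]).
#' @param clean optional function applied to raw names before the binomial
#'   test (e.g. an authority stripper); off by default, so annotated names are
#'   dropped rather than repaired.
#' @return list with tibbles `kept` and `dropped`; together they hold every
#'   input entry.
#' @export
filter_species_level <- function(entries, clean = NULL) {
  nm <- entries$raw_name
  if (!is.null(clean)) nm <- clean(nm)
  ok <- is_binomial(nm)
  list(kept = entries[ok, ], dropped = entries[!ok, ])
}

#' Resolve raw names to valid names with synonym sub-lists
#'
#' Each raw name is looked up in the synonym table (case-insensitively, after
#' genus/epithet case normalization). Names found there map to their valid
#' name; names absent resolve to themselves with no synonyms and status
#' `self_unresolved` (they stay in all downstream counts under their own
#' name). Raw names sharing a valid name merge into one taxon. Each taxon
#' carries its search sub-list: the valid name first, then every synonym the
#' table records for it.
#'
#' @param raw_names character vector (or set) of binomial names.
#' @param table synonym table ([read_synonym_table()]); validated before use.
#' @param groups optional named character vector mapping raw names to taxon
#'   groups; a merged taxon takes the group of its alphabetically first source
#'   name.
#' @return a tibble of resolved taxa, sorted by `valid_name`, with columns
#'   `valid_name`, `taxon_group`, `synonyms` (list), `search_list` (list,
#'   valid name first), `source_names` (list), `n_sources`. The per-raw-name
#'   resolution report (columns `raw_name`, `valid_name`, `status` in
#'   accepted/synonym/self_unresolved) is attached as attribute `"report"`,
#'   see [resolution_report()].
#' @export
resolve_names <- function(raw_names, table, groups = NULL) {
  table <- validate_synonym_table(table)
  raw_names <- unique(as.character(raw_names))
  if (any(!is_binomial(raw_names))) {
    abort("resolve_names() expects species-level binomials; run filter_species_level() first")
  }
  key <- norm_species(raw_names)
  tab_key <- norm_species(table$raw_name)
  hit <- match(key, tab_key)

  valid <- as.character(ifelse(is.na(hit), norm_species(raw_names),
                               norm_species(table$valid_name[hit])))
  # display form of the valid name: prefer the table's spelling, else the raw name
  valid_disp <- as.character(ifelse(is.na(hit), norm_species(raw_names),
                                    table$valid_name[hit]))
  status <- as.character(ifelse(is.na(hit), "self_unresolved",
                                ifelse(table$status[hit] == "synonym",
                                       "synonym", "accepted")))

  report <- tibble(raw_name = raw_names, valid_name = valid_disp,
                   status = status) |> arrange(.data$raw_name)

  syn_rows <- table[table$status == "synonym", ]
  syn_by_valid <- split(syn_rows$raw_name, norm_species(syn_rows$valid_name))

  taxa <- tibble(valid_key = valid, valid_name = valid_disp,
                 source = raw_names) |>
    group_by(.data$valid_key) |>
    summarise(
      valid_name = .data$valid_name[1],
      source_names = list(sort(.data$source)),
      .groups = "drop"
    )
  taxa$synonyms <- purrr::map2(taxa$valid_key, taxa$valid_name, function(k, v) {
    s <- unique(syn_by_valid[[k]] %||% character(0))
    setdiff(s, v)
  })
  taxa$search_list <- purrr::map2(taxa$valid_name, taxa$synonyms,
                                  function(v, s) c(v, s))
  if (!is.null(groups)) {
    first_src <- vapply(taxa$source_names, function(s) s[[1]], character(1))
    taxa$taxon_group <- unname(groups[first_src])
    taxa$taxon_group[is.na(taxa$taxon_group)] <- "unassigned"
  } else {
    taxa$taxon_group <- "unassigned"
  }
  taxa$n_sources <- lengths(taxa$source_names)
  taxa <- taxa |>
    select("valid_name", "taxon_group", "synonyms", "search_list",
           "source_names", "n_sources") |>
    arrange(.data$valid_name)
  attr(taxa, "report") <- report
  taxa
}

#' Per-raw-name resolution report
#'
#' @param taxa result of [resolve_names()].
#' @return tibble `raw_name`, `valid_name`, `status`.
#' @export
resolution_report <- function(taxa) {
  attr(taxa, "report") %||%
    abort("no resolution report attached; pass the result of resolve_names()")
}
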