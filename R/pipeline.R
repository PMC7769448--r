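# End-to-end orchestration: checklist -> species-level filter -> synonym
# resolution -> barcode matching -> BIN audit -> coverage/shared-species
# reports. The command-line front-end (inst/cli/barcodegap.R) is a thin
# wrapper over these functions.

#' Run the full gap analysis
#'
#' Chains every stage on in-memory inputs and returns all intermediate and
#' final tables. Running the stages separately on intermediate files gives
#' identical output; every stage is deterministic.
#'
#' @param checklist checklist tibble ([read_checklist()]).
#' @param synonyms synonym table ([read_synonym_table()]).
#' @param store record store ([read_barcode_records()]).
#' @param region a [region_spec()].
#' @param min_barcodes data-deficiency threshold for the audit.
#' @param public_only_distribution see [classify_species()].
#' @param clean optional raw-name pre-cleaning hook, see
#'   [filter_species_level()].
#' @return a list of class `gap_analysis`: `taxa`, `resolution` (per-raw-name
#'   report), `dropped` (non-binomial entries), `summaries`, `collisions`,
#'   `audit`, `audit_composition`, `uncertainty`, `coverage`,
#'   `shared_species`, `group_composition`, `geo_points`, and `log` (a named
#'   list of stage counts).
#' @export
run_gap_analysis <- function(checklist, synonyms, store, region,
                             min_barcodes = 3,
                             public_only_distribution = TRUE,
                             clean = NULL) {
  split <- filter_species_level(checklist, clean = clean)
  kept <- split$kept

  groups_map <- kept |>
    distinct(.data$raw_name, .keep_all = TRUE)
  groups <- stats::setNames(groups_map$taxon_group, groups_map$raw_name)

  taxa <- resolve_names(unique(kept$raw_name), synonyms, groups = groups)
  report <- resolution_report(taxa)

  summaries <- classify_species(taxa, store, region,
                                public_only_distribution = public_only_distribution)
  audit <- audit_species(summaries, taxa, store, min_barcodes = min_barcodes)
  composition <- audit_composition(audit)

  coverage <- coverage_table(summaries)

  species_countries <- kept |>
    left_join(report |> select("raw_name", "valid_name"), by = "raw_name") |>
    filter(!is.na(.data$country)) |>
    distinct(.data$valid_name, .data$country, .data$taxon_group)

  shared <- shared_species_datasets(summaries, species_countries)
  comp_by_country <- group_composition(species_countries)

  label_groups <- stats::setNames(
    rep(taxa$taxon_group, lengths(taxa$search_list)),
    unlist(taxa$search_list))
  geo_points <- export_geo_points(store, region, group_by = label_groups)

  log <- list(
    n_entries = nrow(checklist),
    n_dropped_nonbinomial = nrow(split$dropped),
    n_raw_names = length(unique(kept$raw_name)),
    n_taxa = nrow(taxa),
    n_unresolved = sum(report$status == "self_unresolved"),
    n_records = nrow(store),
    n_species_barcoded = sum(summaries$availability != "none"),
    n_species_public = sum(summaries$availability == "public"),
    n_species_inside = sum(summaries$distribution == "inside"),
    n_species_audited = nrow(audit),
    n_match_collisions = nrow(match_collisions(summaries))
  )

  structure(list(
    taxa = taxa,
    resolution = report,
    dropped = split$dropped,
    summaries = summaries,
    collisions = match_collisions(summaries),
    audit = audit,
    audit_composition = composition,
    uncertainty = attr(composition, "uncertainty"),
    coverage = coverage,
    shared_species = shared,
    group_composition = comp_by_country,
    geo_points = geo_points,
    log = log
  ), class = "gap_analysis")
}

#' @export
print.gap_analysis <- function(x, ...) {
  l <- x$log
  cat("<gap_analysis>\n",
      "  checklist entries: ", l$n_entries,
      " (", l$n_dropped_nonbinomial, " non-binomial dropped)\n",
      "  resolved taxa:     ", l$n_taxa,
      " (", l$n_unresolved, " unresolved, kept under own name)\n",
      "  barcoded species:  ", l$n_species_barcoded,
      " of which public: ", l$n_species_public,
      ", with in-region public record: ", l$n_species_inside, "\n",
      "  audited species:   ", l$n_species_audited, "\n", sep = "")
  invisible(x)
}

#' Report bundle of a gap analysis
#'
#' The named list of flat tables [write_report()] serializes.
#'
#' @param results a [run_gap_analysis()] result.
#' @return named list of tibbles.
#' @export
gap_tables <- function(results) {
  list(
    resolution = results$resolution,
    match_summary = match_summary_table(results$summaries),
    collisions = results$collisions,
    audit = results$audit,
    audit_composition = results$audit_composition,
    uncertainty = results$uncertainty,
    coverage = results$coverage |>
      rename(species_obis = "n_obis", species_bold = "n_bold",
             species_sep = "n_sep"),
    shared_species = results$shared_species |>
      select("dataset", "countries", "n_species"),
    group_composition = results$group_composition
  )
}

#' Run the gap analysis from files
#'
#' @param checklist_path,synonyms_path,records_path input file paths
#'   (checklist dialect inferred from extension: `.json` -> OBIS JSON,
#'   otherwise TSV).
#' @param region a [region_spec()] or character vector of member countries.
#' @param markers marker allow-list for [read_barcode_records()].
#' @inheritParams run_gap_analysis
#' @return a `gap_analysis` list, see [run_gap_analysis()].
#' @export
run_gap_analysis_files <- function(checklist_path, synonyms_path, records_path,
                                   region, markers = "COI-5P",
                                   min_barcodes = 3,
                                   public_only_distribution = TRUE) {
  if (!inherits(region, "region_spec")) {
    region <- region_spec("region", region)
  }
  dialect <- if (grepl("\\.json$", checklist_path, ignore.case = TRUE))
    "obis_json" else "tsv"
  run_gap_analysis(
    checklist = read_checklist(checklist_path, dialect = dialect),
    synonyms = read_synonym_table(synonyms_path),
    store = read_barcode_records(records_path, markers = markers),
    region = region,
    min_barcodes = min_barcodes,
    public_only_distribution = public_only_distribution
  )
}
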