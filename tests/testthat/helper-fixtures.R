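# In-code fixture builders shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A record-store tibble from compact per-record arguments; unspecified fields
# get innocuous defaults (public, vouchered, not mined, no coordinates).
make_store <- function(species, bin = NA_character_, visibility = "public",
                       country = NA_character_, lat = NA_real_, lon = NA_real_,
                       voucher = "vouchered", mined = FALSE,
                       marker = "COI-5P", id = NULL) {
  m <- length(species)
  df <- tibble::tibble(
    record_id = id %||% sprintf("R%03d", seq_len(m)),
    species_label = species,
    marker = rep_len(marker, m),
    bin_id = rep_len(bin, m),
    visibility = rep_len(visibility, m),
    country = rep_len(country, m),
    lat = rep_len(lat, m),
    lon = rep_len(lon, m),
    voucher_status = rep_len(voucher, m),
    mined_from_genbank = rep_len(mined, m)
  )
  as_barcode_store(df)
}

make_checklist <- function(raw_name, area_id = "area_1",
                           country = "Peru", taxon_group = "Actinopterygii") {
  tibble::tibble(
    raw_name = raw_name,
    area_id = rep_len(area_id, length(raw_name)),
    country = rep_len(country, length(raw_name)),
    taxon_group = rep_len(taxon_group, length(raw_name))
  )
}

# identity synonym table (every name accepted) plus optional synonym pairs
make_synonyms <- function(valid, synonym_of = character(0)) {
  acc <- tibble::tibble(raw_name = valid, valid_name = valid,
                        status = "accepted")
  if (length(synonym_of) > 0) {
    acc <- dplyr::bind_rows(acc, tibble::tibble(
      raw_name = names(synonym_of), valid_name = unname(synonym_of),
      status = "synonym"))
  }
  acc
}

sep_region <- function() {
  region_spec("SEP", c("Colombia", "Ecuador", "Peru", "Chile"))
}

# small universe configs for property loops
small_config <- function(seed, ...) {
  defaults <- list(
    seed = seed,
    n_species_per_group = c(GroupA = 5, GroupB = 4, GroupC = 3),
    countries = c("Chile", "Peru", "Ecuador", "Colombia"),
    synonym_rate = 0.3,
    barcode_coverage = 0.8,
    public_fraction = 0.8,
    in_region_fraction = 0.4,
    grade_mix = c("AB" = 0.2, "C" = 0.15, "D" = 0.2, "E*" = 0.15,
                  "E**" = 0.1, "F" = 0.2),
    records_per_species_range = c(3L, 5L),
    nonbinomial_rate = 0.15
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(universe_config, args)
}

run_universe <- function(uni, ...) {
  run_gap_analysis(uni$checklist, uni$synonyms, uni$records, uni$region, ...)
}
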