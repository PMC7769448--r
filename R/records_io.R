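# Readers and writers for the three external inputs (checklist, barcode
# records, synonym table) and the report/point-set outputs. The rest of the
# pipeline never touches files directly, so a live OBIS/WoRMS/BOLD adapter
# only has to produce the same tibbles these readers produce (see the
# "Adapter contracts" section of the methods vignette).

CHECKLIST_COLS <- c("raw_name", "area_id", "country", "taxon_group")
BARCODE_COLS <- c("record_id", "species_label", "marker", "bin_id",
                  "visibility", "country", "lat", "lon", "voucher_status",
                  "mined_from_genbank")
SYNONYM_COLS <- c("raw_name", "valid_name", "status")

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) abort(paste0(what, " file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"), progress = FALSE,
                        show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0("malformed ", what, " row(s) at line(s) ",
                 paste(unique(probs$row + 1L), collapse = ", "),
                 " of ", path))
  }
  df
}

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Read a species checklist
#'
#' Reads a regional species checklist, either as a four-column TSV
#' (`raw_name`, `area_id`, `country`, `taxon_group`) or as OBIS-checklist-style
#' JSON: an array of objects each carrying `scientificName` plus the query's
#' area id (field `area_id` or `areaId`) and optionally `country` and
#' `taxon_group`.
#'
#' Duplicate (`raw_name`, `area_id`) pairs are collapsed to one entry (first
#' occurrence wins for the remaining fields) and the result is sorted by
#' `raw_name` then `area_id`, so entry order depends only on file content.
#'
#' @param path path to the checklist file.
#' @param dialect `"tsv"` or `"obis_json"`.
#' @param taxon_groups optional character vector: the controlled vocabulary of
#'   taxon groups. Entries whose group is absent from it are flagged
#'   `"unassigned"`. `NULL` (default) accepts any group label.
#' @return a tibble of checklist entries with columns `raw_name`, `area_id`,
#'   `country`, `taxon_group`.
#' @export
read_checklist <- function(path, dialect = c("tsv", "obis_json"),
                           taxon_groups = NULL) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) abort(
                        paste0("unknown checklist dialect: ",
                               paste(dialect, collapse = "/"))))
  if (dialect == "tsv") {
    df <- read_tsv_strict(path, "checklist")
    require_cols(df, CHECKLIST_COLS, "checklist TSV")
    df <- df[CHECKLIST_COLS]
  } else {
    rows <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.list(rows)) abort("OBIS-JSON checklist must be an array of objects")
    df <- purrr::map_dfr(rows, function(r) {
      tibble(
        raw_name = as.character(r$scientificName %||% NA_character_),
        area_id = as.character(r$area_id %||% r$areaId %||% NA_character_),
        country = as.character(r$country %||% NA_character_),
        taxon_group = as.character(r$taxon_group %||% NA_character_)
      )
    })
    if (nrow(df) == 0) df <- tibble(raw_name = character(), area_id = character(),
                                    country = character(), taxon_group = character())
  }
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), blank_to_na))
  bad <- which(is.na(df$raw_name) | is.na(df$area_id))
  if (length(bad) > 0) {
    abort(paste0("checklist row(s) with empty raw_name or area_id at line(s) ",
                 paste(bad + 1L, collapse = ", ")))
  }
  if (!is.null(taxon_groups)) {
    known <- norm_text(df$taxon_group) %in% norm_text(taxon_groups)
    df$taxon_group[!known] <- "unassigned"
  }
  df$taxon_group[is.na(df$taxon_group)] <- "unassigned"
  df |>
    distinct(.data$raw_name, .data$area_id, .keep_all = TRUE) |>
    arrange(.data$raw_name, .data$area_id)
}

#' Write a checklist TSV
#'
#' @param entries checklist tibble as returned by [read_checklist()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(entries, path) {
  readr::write_tsv(entries[CHECKLIST_COLS], path, na = "")
  invisible(path)
}

parse_logical_flag <- function(x) {
  out <- rep(NA, length(x))
  out[norm_text(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[norm_text(x) %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a barcode record store
#'
#' Reads a BOLD-combined-TSV-style table of specimen records. Mandatory
#' columns: `record_id`, `species_label`, `marker`, `bin_id`, `visibility`,
#' `country`, `lat`, `lon`, `voucher_status`, `mined_from_genbank`. Empty
#' strings are treated as missing. Rows whose marker is not in the allow-list
#' are excluded and counted in the skip report (`skip_report(store)`).
#'
#' @param path path to the records TSV.
#' @param markers marker allow-list; records with other markers are skipped.
#'   Default `"COI-5P"`, the animal DNA-barcode fragment.
#' @return a record-store tibble (one row per retained record) with a
#'   `skip_report` attribute, a named integer vector.
#' @export
read_barcode_records <- function(path, markers = "COI-5P") {
  df <- read_tsv_strict(path, "barcode records")
  require_cols(df, BARCODE_COLS, "barcode TSV")
  df <- df[BARCODE_COLS]
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(), blank_to_na))
  as_barcode_store(df, markers = markers)
}

#' Validate a tibble as a barcode record store
#'
#' Applies the same validation and marker filtering as
#' [read_barcode_records()] to an in-memory data frame.
#'
#' @inheritParams read_barcode_records
#' @param df data frame with the barcode column set.
#' @return a record-store tibble with a `skip_report` attribute.
#' @export
as_barcode_store <- function(df, markers = "COI-5P") {
  require_cols(df, BARCODE_COLS, "barcode store")
  df <- as_tibble(df)[BARCODE_COLS]
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  if (!is.logical(df$mined_from_genbank)) {
    df$mined_from_genbank <- parse_logical_flag(df$mined_from_genbank)
  }
  df$mined_from_genbank[is.na(df$mined_from_genbank)] <- FALSE

  dup <- df$record_id[duplicated(df$record_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate record_id in barcode store: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(df$record_id)) || any(is.na(df$species_label))) {
    abort("barcode store rows must have non-missing record_id and species_label")
  }
  bad_coord <- !is.na(df$lat) &
    (abs(df$lat) > 90 | is.na(df$lon) | abs(df$lon) > 180)
  if (any(bad_coord)) {
    abort(paste0("out-of-range or incomplete coordinates for record(s): ",
                 paste(df$record_id[bad_coord], collapse = ", ")))
  }
  vis <- norm_text(df$visibility)
  if (any(!vis %in% c("public", "private"))) {
    abort("visibility must be 'public' or 'private' for every record")
  }
  df$visibility <- vis
  vs <- norm_text(df$voucher_status)
  vs[is.na(vs)] <- "unknown"
  if (any(!vs %in% c("vouchered", "unvouchered", "unknown"))) {
    abort("voucher_status must be vouchered, unvouchered or unknown")
  }
  df$voucher_status <- vs

  keep <- df$marker %in% markers
  skipped <- c("non_allowed_marker" = sum(!keep))
  out <- df[keep, ]
  attr(out, "skip_report") <- skipped
  out
}

#' Skip report of a reader or exporter result
#'
#' @param x object carrying a `skip_report` attribute.
#' @return named integer vector of skipped-row counts (zero-length if none).
#' @export
skip_report <- function(x) {
  attr(x, "skip_report") %||% stats::setNames(integer(0), character(0))
}

#' Write a barcode record store TSV
#'
#' Inverse of [read_barcode_records()]: `read_barcode_records(write_barcode_records(s, p))`
#' reproduces `s` field by field.
#'
#' @param store record-store tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_barcode_records <- function(store, path) {
  out <- store[BARCODE_COLS]
  out$mined_from_genbank <- ifelse(out$mined_from_genbank, "true", "false")
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a synonym table
#'
#' Reads a WoRMS-style synonymy TSV with columns `raw_name`, `valid_name`,
#' `status` (`accepted`/`synonym`/`unresolved`) and checks its invariants:
#' every `accepted` row has `raw_name == valid_name`, and no raw name maps to
#' two different valid names.
#'
#' @param path path to the synonym TSV.
#' @return a validated synonym-table tibble.
#' @export
read_synonym_table <- function(path) {
  df <- read_tsv_strict(path, "synonym table")
  require_cols(df, SYNONYM_COLS, "synonym TSV")
  validate_synonym_table(as_tibble(df[SYNONYM_COLS]))
}

#' Validate a synonym table
#'
#' @param table synonym-table data frame.
#' @return the table, invisibly returned as a tibble, or an error naming the
#'   violated invariant.
#' @export
validate_synonym_table <- function(table) {
  require_cols(table, SYNONYM_COLS, "synonym table")
  table <- as_tibble(table)
  if (!all(table$status %in% c("accepted", "synonym", "unresolved"))) {
    abort("synonym table status must be accepted, synonym or unresolved")
  }
  acc <- table[table$status == "accepted", ]
  if (any(norm_species(acc$raw_name) != norm_species(acc$valid_name))) {
    abort("synonym table invariant violated: an 'accepted' row must map a name to itself")
  }
  key <- norm_species(table$raw_name)
  n_targets <- tapply(norm_species(table$valid_name), key,
                      function(v) length(unique(v)))
  if (any(n_targets > 1)) {
    abort(paste0("synonym table invariant violated: raw name(s) mapped to ",
                 "multiple valid names: ",
                 paste(names(n_targets)[n_targets > 1], collapse = ", ")))
  }
  table
}

#' Write a synonym table TSV
#'
#' @param table synonym-table tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synonym_table <- function(table, path) {
  readr::write_tsv(table[SYNONYM_COLS], path, na = "")
  invisible(path)
}

#' Write a report bundle
#'
#' Serializes a named list of tables, one file per table per requested format.
#' Percentage columns (names starting with `pct_`) are written at one decimal
#' (half away from zero) and proportion columns (`prop` or starting with
#' `prop_`) at three, matching the precision of the package's printed tables;
#' other numeric columns are written as-is.
#'
#' @param tables named list of data frames.
#' @param path output directory (created if absent).
#' @param formats subset of `c("tsv", "json")`.
#' @param pct_digits decimals for `pct_*` columns.
#' @param prop_digits decimals for proportion columns.
#' @return a manifest tibble: `table`, `format`, `file`, `n_rows`.
#' @export
write_report <- function(tables, path, formats = c("tsv", "json"),
                         pct_digits = 1, prop_digits = 3) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (length(tables) > 0 && (is.null(names(tables)) || any(names(tables) == ""))) {
    abort("write_report() needs a named list of tables")
  }
  ok <- tryCatch(dir.exists(path) || dir.create(path, recursive = TRUE),
                 warning = function(w) FALSE)
  if (!ok || !dir.exists(path)) abort(paste0("cannot write to directory: ", path))
  manifest <- tibble(table = character(), format = character(),
                     file = character(), n_rows = integer())
  for (nm in names(tables)) {
    tab <- as_tibble(tables[[nm]])
    out <- tab
    for (col in names(out)) {
      if (!is.numeric(out[[col]])) next
      if (startsWith(col, "pct_")) {
        out[[col]] <- round_half_away(out[[col]], pct_digits)
      } else if (col == "prop" || startsWith(col, "prop_")) {
        out[[col]] <- round_half_away(out[[col]], prop_digits)
      }
    }
    # list-columns (e.g. country subsets) are serialized plus-joined
    for (col in names(out)) {
      if (is.list(out[[col]])) {
        out[[col]] <- vapply(out[[col]], function(v)
          paste(sort(as.character(v)), collapse = "+"), character(1))
      }
    }
    for (fmt in formats) {
      file <- file.path(path, paste0(nm, ".", fmt))
      if (fmt == "tsv") {
        readr::write_tsv(out, file, na = "")
      } else {
        jsonlite::write_json(out, file, dataframe = "rows", na = "null",
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      manifest <- bind_rows(manifest, tibble(
        table = nm, format = fmt, file = file, n_rows = nrow(tab)))
    }
  }
  manifest
}

#' Export sampling points for barcoded specimens
#'
#' One point per record that carries both coordinates, labeled with the
#' species, its taxon group and whether the record is in-region (see
#' [record_in_region()]). Records without coordinates are counted in the skip
#' report. Points at (0, 0) are retained but flagged in `null_island`;
#' coordinate cleaning is deliberately opt-in.
#'
#' @param store record-store tibble.
#' @param region a [region_spec()].
#' @param group_by named character vector mapping species labels (or valid
#'   names) to taxon groups; unmapped species get `"unassigned"`.
#' @return tibble `species`, `taxon_group`, `lat`, `lon`, `in_region`,
#'   `null_island`, with a `skip_report` attribute (`no_coordinates` count).
#' @export
export_geo_points <- function(store, region, group_by = NULL) {
  has_xy <- !is.na(store$lat) & !is.na(store$lon)
  pts <- store[has_xy, ]
  grp <- rep("unassigned", nrow(pts))
  if (!is.null(group_by) && nrow(pts) > 0) {
    hit <- match(norm_species(pts$species_label), norm_species(names(group_by)))
    grp[!is.na(hit)] <- unname(group_by)[hit[!is.na(hit)]]
  }
  out <- tibble(
    species = pts$species_label,
    taxon_group = grp,
    lat = pts$lat,
    lon = pts$lon,
    in_region = record_in_region(pts, region),
    null_island = pts$lat == 0 & pts$lon == 0
  )
  attr(out, "skip_report") <- c(no_coordinates = sum(!has_xy))
  out
}

#' Write a point set as CSV and GeoJSON
#'
#' @param points tibble from [export_geo_points()].
#' @param dir output directory.
#' @param name file stem (writes `<name>.csv` and `<name>.geojson`).
#' @return character vector of the two file paths, invisibly.
#' @export
write_geo_points <- function(points, dir, name = "geo_points") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  readr::write_csv(points[c("species", "taxon_group", "lat", "lon", "in_region")],
                   csv, na = "")
  features <- purrr::pmap(points, function(species, taxon_group, lat, lon,
                                           in_region, ...) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(lon, lat)),
      properties = list(species = species, taxon_group = taxon_group,
                        in_region = in_region)
    )
  })
  gj <- file.path(dir, paste0(name, ".geojson"))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       gj, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, geojson = gj))
}
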