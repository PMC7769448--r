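test_that("checklist TSV reading collapses duplicates and sorts deterministically", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "raw_name\tarea_id\tcountry\ttaxon_group",
    "Engraulis ringens\tarea_peru\tPeru\tActinopterygii",
    "Mola mola\tarea_chile\tChile\tActinopterygii",
    "Engraulis ringens\tarea_peru\tPeru\tActinopterygii"
  ), path)
  entries <- read_checklist(path)
  expect_equal(nrow(entries), 2)
  expect_equal(entries$raw_name, c("Engraulis ringens", "Mola mola"))

  # header-only file is an empty checklist, not an error
  writeLines("raw_name\tarea_id\tcountry\ttaxon_group", path)
  expect_equal(nrow(read_checklist(path)), 0)
})

test_that("checklist entries keep their area id (count checked by line scan)", {
  path <- withr::local_tempfile(fileext = ".tsv")
  species <- paste("Genus", letters[1:10])
  areas <- rep(c("area_1", "area_2"), 5)
  writeLines(c("raw_name\tarea_id\tcountry\ttaxon_group",
               paste(species, areas, "Peru", "Mollusca", sep = "\t")), path)
  n_expected <- length(readLines(path)) - 1L # independent line scan
  entries <- read_checklist(path)
  expect_equal(nrow(entries), n_expected)
  expect_equal(sort(unique(entries$area_id)), c("area_1", "area_2"))
  expect_equal(entries$area_id[entries$raw_name == "Genus b"], "area_2")
})

test_that("checklist reader rejects bad input with line numbers and unknown dialects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("raw_name\tarea_id\tcountry\ttaxon_group",
               "Mola mola\t\tChile\tActinopterygii"), path)
  expect_error(read_checklist(path), "line\\(s\\) 2")
  expect_error(read_checklist(path, dialect = "csv"), "dialect")

  writeLines(c("raw_name\tcountry", "Mola mola\tChile"), path)
  expect_error(read_checklist(path), "area_id")
})

test_that("checklist taxon groups outside the vocabulary are flagged unassigned", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("raw_name\tarea_id\tcountry\ttaxon_group",
               "Mola mola\ta1\tChile\tActinopterygii",
               "Aplysia punctata\ta1\tChile\tWeirdGroup"), path)
  entries <- read_checklist(path, taxon_groups = c("Actinopterygii", "Mollusca"))
  expect_equal(entries$taxon_group,
               c("Aplysia punctata" = "unassigned",
                 "Mola mola" = "Actinopterygii")[entries$raw_name] |> unname())
})

test_that("OBIS-style JSON checklists are read like their TSV twins", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(scientificName = "Mola mola", area_id = "a1", country = "Chile",
         taxon_group = "Actinopterygii"),
    list(scientificName = "Aplysia punctata", areaId = "a2")
  ), path, auto_unbox = TRUE)
  entries <- read_checklist(path, dialect = "obis_json")
  expect_equal(entries$raw_name, c("Aplysia punctata", "Mola mola"))
  expect_equal(entries$area_id, c("a2", "a1"))
  expect_equal(entries$taxon_group, c("unassigned", "Actinopterygii"))
})

test_that("barcode reader filters markers into the skip report and keeps totals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  store <- make_store(c("Mola mola", "Mola mola", "Aplysia punctata",
                        "Aplysia punctata", "Mola mola"),
                      bin = "BOLD:AAA0001")
  store$marker[3] <- "16S"
  write_barcode_records(store, path)
  got <- read_barcode_records(path)
  expect_equal(nrow(got), 4)
  expect_equal(skip_report(got), c(non_allowed_marker = 1L))
  # loaded + skipped = total input rows
  expect_equal(nrow(got) + sum(skip_report(got)), nrow(store))
  # widening the allow-list recovers the record
  expect_equal(nrow(read_barcode_records(path, markers = c("COI-5P", "16S"))), 5)
})

test_that("empty bin_id reads as absent and duplicate ids or missing columns error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("record_id", "species_label", "marker", "bin_id", "visibility",
            "country", "lat", "lon", "voucher_status", "mined_from_genbank"),
          collapse = "\t"),
    "R1\tMola mola\tCOI-5P\t\tpublic\tChile\t\t\tvouchered\tfalse"
  ), path)
  got <- read_barcode_records(path)
  expect_true(is.na(got$bin_id[1]))

  expect_error(make_store(c("A a", "B b"), id = c("R1", "R1")),
               "duplicate record_id")
  expect_error(as_barcode_store(tibble::tibble(record_id = "R1")),
               "missing mandatory column")
})

test_that("a record store round-trips through TSV field by field", {
  uni <- generate_universe(small_config(11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_barcode_records(uni$records, path)
  back <- read_barcode_records(path)
  orig <- uni$records
  attributes(orig)$skip_report <- NULL
  attributes(back)$skip_report <- NULL
  expect_equal(as.data.frame(back), as.data.frame(orig))
})

test_that("coordinate sanity is enforced at load time", {
  df <- make_store("Mola mola")
  df$lat <- 95
  df$lon <- 10
  expect_error(as_barcode_store(df), "coordinates")
})

test_that("write_report writes one file per table per format with a manifest", {
  dir <- withr::local_tempdir()
  cov <- coverage_from_counts(tibble::tibble(
    group = c("Mammalia", "Reptilia", "Aves"),
    n_obis = c(40, 6, 10), n_bold = c(35, 6, 2), n_sep = c(3, 2, 0)))
  manifest <- write_report(list(coverage = cov), dir, formats = "tsv")
  expect_equal(nrow(manifest), 1)
  expect_equal(manifest$n_rows, 4) # three groups + totals row
  expect_true(file.exists(file.path(dir, "coverage.tsv")))

  # empty bundle: empty manifest, no files
  dir2 <- withr::local_tempdir()
  m2 <- write_report(list(), dir2)
  expect_equal(nrow(m2), 0)
  expect_equal(length(list.files(dir2)), 0)
})

test_that("the exported coverage TSV carries the documented header and precision", {
  uni <- generate_universe(small_config(3))
  res <- run_universe(uni)
  dir <- withr::local_tempdir()
  write_report(gap_tables(res)["coverage"], dir, formats = "tsv")
  lines <- readLines(file.path(dir, "coverage.tsv"))
  expect_equal(lines[1],
               "group\tspecies_obis\tspecies_bold\tpct_bold\tspecies_sep\tpct_sep")
  # percentage cells serialized at one decimal
  pct <- read.delim(file.path(dir, "coverage.tsv"))$pct_bold
  expect_equal(pct, round_half_away(res$coverage$pct_bold, 1))
})

test_that("geo-point export keeps complete coordinates and counts the rest", {
  store <- make_store(c("Mola mola", "Mola mola", "Aplysia punctata"),
                      country = "Chile",
                      lat = c(-33.1, NA, 0), lon = c(-71.6, -70.0, 0))
  pts <- export_geo_points(store, sep_region(),
                           group_by = c("Mola mola" = "Actinopterygii"))
  expect_equal(nrow(pts), 2)
  expect_equal(skip_report(pts), c(no_coordinates = 1L))
  expect_true(all(pts$in_region)) # country Chile decides, not coordinates
  # (0,0) is retained but flagged, never silently cleaned
  expect_equal(pts$null_island, c(FALSE, TRUE))
  expect_equal(pts$taxon_group, c("Actinopterygii", "unassigned"))
})

test_that("polygon fallback labels in-region points when country is missing", {
  square <- cbind(lat = c(-10, -10, 10, 10), lon = c(-10, 10, 10, -10))
  region <- region_spec("box", "Atlantis", bounding_polygon = square)
  inside_lat <- c(-5, 0, 5, 9, -9)
  outside_lat <- c(50, -50, 11)
  store <- make_store(rep("Mola mola", 8),
                      lat = c(inside_lat, outside_lat),
                      lon = c(rep(0, 5), 20, 0, 0))
  pts <- export_geo_points(store, region)
  expect_equal(pts$in_region, c(rep(TRUE, 5), rep(FALSE, 3)))
  gj_dir <- withr::local_tempdir()
  files <- write_geo_points(pts, gj_dir)
  gj <- jsonlite::fromJSON(files[["geojson"]], simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 8)
  expect_equal(gj$features[[1]]$geometry$coordinates[[2]], -5) # lon first, lat second
})
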