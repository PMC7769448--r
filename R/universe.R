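# Synthetic universe: internally consistent checklist + synonym table +
# barcode store with planted, exactly recoverable truth for every downstream
# statistic. Fractions are realized by deterministic largest-remainder quota
# allocation, not Bernoulli sampling, so recovery tests are exact.

OUTSIDE_COUNTRIES <- c("Japan", "France", "Australia", "South Africa",
                       "Canada", "Norway")

#' Configuration for a synthetic universe
#'
#' Defaults emulate the statistical shape of a regional marine gap analysis:
#' 1000 checklist species across ten taxon groups, four countries forming the
#' focal region, 42% of species with at least one barcode record, and a grade
#' mix dominated by concordant and data-deficient species.
#'
#' @param seed integer RNG seed; the generator is a pure function of the
#'   config, so a fixed seed gives byte-identical output.
#' @param n_species_per_group named integer vector, species per taxon group.
#' @param countries countries of the focal region (each species is reported
#'   from a non-empty subset of them).
#' @param synonym_rate fraction of species given one junior synonym; the
#'   synonym is used as the checklist label in the species' first country and
#'   on one barcode record, to exercise sub-list matching.
#' @param barcode_coverage fraction of species with >= 1 barcode record.
#' @param public_fraction fraction of barcoded species with >= 1 public record
#'   (the rest are private-only).
#' @param in_region_fraction fraction of public species with an in-region
#'   public record.
#' @param grade_mix named fractions over `c("AB","C","D","E*","E**","F")`
#'   (must sum to 1) for the audit grades planted among public species.
#' @param records_per_species_range integer `(min, max)` records for graded
#'   species (clipped up to what a grade requires; grade D species always get
#'   fewer than `min_barcodes`).
#' @param nonbinomial_rate fraction of checklist entries that are
#'   non-species-level labels (`sp.`, `cf.`, authority strings), planted to
#'   exercise the binomial filter.
#' @param min_barcodes the data-deficiency threshold the records are
#'   constructed against.
#' @return a validated `universe_config` list.
#' @export
universe_config <- function(seed = 1,
                            n_species_per_group = c(
                              Actinopterygii = 260, Arthropoda = 250,
                              Mollusca = 155, Cnidaria = 75, Annelida = 73,
                              Echinodermata = 68, Other_invertebrates = 84,
                              Elasmobranchii = 24, Mammalia = 7, Reptilia = 4),
                            countries = c("Chile", "Peru", "Ecuador", "Colombia"),
                            synonym_rate = 0.2,
                            barcode_coverage = 0.42,
                            public_fraction = 0.7,
                            in_region_fraction = 0.15,
                            grade_mix = c("AB" = 0.25, "C" = 0.10, "D" = 0.35,
                                          "E*" = 0.05, "E**" = 0.05, "F" = 0.20),
                            records_per_species_range = c(3L, 6L),
                            nonbinomial_rate = 0.1,
                            min_barcodes = 3) {
  frac <- c(synonym_rate = synonym_rate, barcode_coverage = barcode_coverage,
            public_fraction = public_fraction,
            in_region_fraction = in_region_fraction,
            nonbinomial_rate = nonbinomial_rate)
  if (any(frac < 0 | frac > 1)) {
    abort(paste0("fractions must lie in [0, 1]: ",
                 paste(names(frac)[frac < 0 | frac > 1], collapse = ", ")))
  }
  if (nonbinomial_rate >= 1) abort("nonbinomial_rate must be < 1")
  if (is.null(names(n_species_per_group)) || any(n_species_per_group < 0)) {
    abort("n_species_per_group must be a named non-negative integer vector")
  }
  if (length(countries) < 1) abort("at least one country is required")
  if (!setequal(names(grade_mix), AUDIT_GRADES)) {
    abort(paste0("grade_mix must name exactly the grades ",
                 paste(AUDIT_GRADES, collapse = ", ")))
  }
  if (any(grade_mix < 0) || abs(sum(grade_mix) - 1) > 1e-9) {
    abort("grade_mix fractions must be non-negative and sum to 1")
  }
  r <- as.integer(records_per_species_range)
  if (length(r) != 2 || r[1] < 1 || r[2] < r[1]) {
    abort("records_per_species_range must be (min, max) with min >= 1")
  }
  if (min_barcodes < 1) abort("min_barcodes must be >= 1")
  if (min_barcodes == 1 && grade_mix[["D"]] > 0) {
    abort("infeasible grade_mix: no species can be data deficient (D) when min_barcodes is 1")
  }
  structure(list(
    seed = as.integer(seed),
    n_species_per_group = n_species_per_group,
    countries = as.character(countries),
    synonym_rate = synonym_rate,
    barcode_coverage = barcode_coverage,
    public_fraction = public_fraction,
    in_region_fraction = in_region_fraction,
    grade_mix = grade_mix[AUDIT_GRADES],
    records_per_species_range = r,
    nonbinomial_rate = nonbinomial_rate,
    min_barcodes = min_barcodes
  ), class = "universe_config")
}

new_bin_id <- function(i) {
  # BOLD:AAA0001-shaped identifiers, unique per index
  letters3 <- function(n) {
    a <- (n - 1L) %/% 676L
    b <- ((n - 1L) %/% 26L) %% 26L
    c0 <- (n - 1L) %% 26L
    paste0(LETTERS[a + 1L], LETTERS[b + 1L], LETTERS[c0 + 1L])
  }
  sprintf("BOLD:%s%04d", letters3((i - 1L) %/% 10000L + 1L), i %% 10000L)
}

#' Generate a synthetic universe
#'
#' Produces a checklist, a synonym table, a barcode record store and a truth
#' ledger. Record sets are constructed to earn their planted audit grade under
#' the grading rules (e.g. a grade-C species gets vouchered records split over
#' two BINs exclusive to it; E*/E** species share a BIN with a dedicated
#' off-checklist partner species whose records are in the store but not on
#' the checklist).
#'
#' @param config a [universe_config()].
#' @return list of class `barcode_universe` with elements `checklist`,
#'   `synonyms`, `records` (a validated record store), `truth` (per-species
#'   ledger tibble), `region` (the implied [region_spec()]) and `config`.
#' @export
generate_universe <- function(config = universe_config()) {
  stopifnot(inherits(config, "universe_config"))
  withr::with_seed(config$seed, generate_universe_impl(config))
}

generate_universe_impl <- function(cfg) {
  groups <- rep(names(cfg$n_species_per_group), cfg$n_species_per_group)
  n <- length(groups)
  if (n == 0) abort("universe must contain at least one species")
  k <- length(cfg$countries)

  idx <- seq_len(n)
  genus <- paste0(toupper(substr(latin_word((idx - 1L) %/% 4L), 1, 1)),
                  substr(latin_word((idx - 1L) %/% 4L), 2, 100L))
  valid_name <- paste(genus, latin_word(1000L + idx))

  # country membership: subset size weighted toward single-country species
  size_probs <- rev(seq_len(k)) / sum(seq_len(k))
  sizes <- sample(seq_len(k), n, replace = TRUE, prob = size_probs)
  countries <- lapply(sizes, function(s) sample(cfg$countries, s))

  # synonym planting (exact quota, random positions)
  n_syn <- quota_counts(n, c(cfg$synonym_rate, 1 - cfg$synonym_rate))[1]
  syn_idx <- sort(sample(n, n_syn))
  synonym <- rep(NA_character_, n)
  synonym[syn_idx] <- paste(genus[syn_idx], latin_word(500000L + syn_idx))

  # availability planting
  n_bar <- quota_counts(n, c(cfg$barcode_coverage, 1 - cfg$barcode_coverage))[1]
  bar_idx <- sort(sample(n, n_bar))
  n_pub <- quota_counts(n_bar, c(cfg$public_fraction, 1 - cfg$public_fraction))[1]
  pub_idx <- sort(safe_sample(bar_idx, n_pub))
  priv_idx <- setdiff(bar_idx, pub_idx)
  n_in <- quota_counts(n_pub, c(cfg$in_region_fraction, 1 - cfg$in_region_fraction))[1]
  in_idx <- sort(safe_sample(pub_idx, n_in))

  # grade planting among public species
  grade <- rep(NA_character_, n)
  g_counts <- quota_counts(n_pub, cfg$grade_mix)
  grade[safe_sample(pub_idx)] <- rep(names(g_counts), g_counts)

  availability <- rep("none", n)
  availability[priv_idx] <- "private_only"
  availability[pub_idx] <- "public"
  distribution <- rep("not_applicable", n)
  distribution[pub_idx] <- "outside"
  distribution[in_idx] <- "inside"

  # ---- checklist -----------------------------------------------------------
  area_of <- function(cty) paste0("area_", gsub(" ", "_", tolower(cty)))
  cl_rows <- purrr::map_dfr(idx, function(i) {
    ctys <- countries[[i]]
    labels <- rep(valid_name[i], length(ctys))
    if (!is.na(synonym[i])) labels[1] <- synonym[i]
    tibble(raw_name = labels, area_id = area_of(ctys), country = ctys,
           taxon_group = groups[i])
  })
  n_clean <- nrow(cl_rows)
  n_junk <- round(n_clean * cfg$nonbinomial_rate / (1 - cfg$nonbinomial_rate))
  if (n_junk > 0) {
    jg <- paste0(toupper(substr(latin_word(800000L + seq_len(n_junk)), 1, 1)),
                 substr(latin_word(800000L + seq_len(n_junk)), 2, 100L))
    pattern <- seq_len(n_junk) %% 3L
    junk_names <- ifelse(pattern == 0L, paste(jg, "sp."),
                         ifelse(pattern == 1L, paste(jg, "cf. dubius"),
                                paste(jg, "dubius Smith, 1901")))
    jc <- sample(cfg$countries, n_junk, replace = TRUE)
    cl_rows <- bind_rows(cl_rows, tibble(
      raw_name = junk_names, area_id = area_of(jc), country = jc,
      taxon_group = sample(names(cfg$n_species_per_group), n_junk,
                           replace = TRUE)))
  }
  checklist <- cl_rows |>
    distinct(.data$raw_name, .data$area_id, .keep_all = TRUE) |>
    arrange(.data$raw_name, .data$area_id)

  # ---- synonym table -------------------------------------------------------
  synonyms <- bind_rows(
    tibble(raw_name = valid_name, valid_name = valid_name,
           status = "accepted"),
    tibble(raw_name = synonym[syn_idx], valid_name = valid_name[syn_idx],
           status = "synonym")
  ) |> arrange(.data$raw_name)

  # ---- barcode records -----------------------------------------------------
  rec_env <- new.env()
  rec_env$rows <- vector("list", 4L * n + 16L)
  rec_env$n_rows <- 0L
  rec_env$rec_i <- 0L
  rec_env$bin_i <- 0L
  next_bin <- function() {
    rec_env$bin_i <- rec_env$bin_i + 1L
    new_bin_id(rec_env$bin_i)
  }
  out_country <- function(m) sample(OUTSIDE_COUNTRIES, m, replace = TRUE)
  coords_for <- function(ctys) {
    m <- length(ctys)
    inside <- ctys %in% cfg$countries
    lat <- ifelse(inside, stats::runif(m, -40, 5), stats::runif(m, 20, 60))
    lon <- ifelse(inside, stats::runif(m, -85, -70), stats::runif(m, 0, 150))
    drop <- stats::runif(m) < 0.15
    lat[drop] <- NA_real_
    lon[drop] <- NA_real_
    list(lat = round(lat, 4), lon = round(lon, 4))
  }
  emit <- function(label, bin, visibility, cty, voucher = "vouchered",
                   mined = FALSE) {
    m <- length(label)
    rec_env$rec_i <- rec_env$rec_i + m
    xy <- coords_for(cty)
    rec_env$n_rows <- rec_env$n_rows + 1L
    rec_env$rows[[rec_env$n_rows]] <- tibble(
      record_id = sprintf("REC%06d", rec_env$rec_i - m + seq_len(m)),
      species_label = label, marker = "COI-5P", bin_id = bin,
      visibility = visibility, country = cty, lat = xy$lat, lon = xy$lon,
      voucher_status = voucher, mined_from_genbank = mined)
  }
  draw_n <- function(at_least = 1L) {
    r <- cfg$records_per_species_range
    max(at_least, safe_sample(seq(r[1], r[2]), 1))
  }
  partner_i <- 0L
  partner_names <- character(0)
  new_partner <- function() {
    partner_i <<- partner_i + 1L
    w <- latin_word(700000L + partner_i)
    nm <- paste(paste0(toupper(substr(w, 1, 1)), substr(w, 2, 100L)),
                latin_word(900000L + partner_i))
    partner_names <<- c(partner_names, nm)
    nm
  }
  n_records_planted <- rep(0L, n)

  for (i in bar_idx) {
    home <- countries[[i]][1] # always a region country
    labels_for <- function(m) {
      lab <- rep(valid_name[i], m)
      if (!is.na(synonym[i]) && m > 1) lab[m] <- synonym[i]
      lab
    }
    if (availability[i] == "private_only") {
      m <- draw_n()
      cty <- if (i %% 2 == 0) c(home, out_country(m - 1)) else out_country(m)
      emit(labels_for(m), rep(next_bin(), m), "private", cty[seq_len(m)])
      n_records_planted[i] <- m
      next
    }
    g <- grade[i]
    pub_cty <- function(m) {
      # first public record in-region iff the species is planted "inside"
      if (distribution[i] == "inside") c(home, out_country(m - 1))[seq_len(m)]
      else out_country(m)
    }
    if (g == "D") {
      m <- safe_sample(seq_len(cfg$min_barcodes - 1), 1)
      emit(labels_for(m), rep(next_bin(), m), "public", pub_cty(m))
    } else if (g == "AB") {
      m <- draw_n(cfg$min_barcodes)
      voucher <- rep("vouchered", m)
      if (i %% 2 == 0) voucher[m] <- "unknown" # unknown counts as vouchered
      emit(labels_for(m), rep(next_bin(), m), "public", pub_cty(m),
           voucher = voucher)
    } else if (g == "C") {
      m <- draw_n(max(cfg$min_barcodes, 2L))
      bins <- c(next_bin(), next_bin())
      emit(labels_for(m), bins[c(1L, rep(2L, m - 1L))], "public", pub_cty(m))
    } else if (g == "E*") {
      m <- draw_n(cfg$min_barcodes)
      shared <- next_bin()
      emit(labels_for(m), rep(shared, m), "public", pub_cty(m))
      emit(new_partner(), shared, "public", out_country(1))
    } else if (g == "E**") {
      m <- draw_n(max(cfg$min_barcodes, 2L))
      shared <- next_bin()
      own <- next_bin()
      emit(labels_for(m), c(shared, rep(own, m - 1L)), "public", pub_cty(m))
      emit(new_partner(), shared, "public", out_country(1))
    } else { # F: whole species unvouchered or GenBank-mined
      m <- draw_n(1L)
      if (i %% 2 == 0) {
        emit(labels_for(m), rep(next_bin(), m), "public", pub_cty(m),
             voucher = "unvouchered")
      } else {
        emit(labels_for(m), rep(next_bin(), m), "public", pub_cty(m),
             mined = TRUE)
      }
    }
    n_records_planted[i] <- m # partner records belong to the partner species
    if (availability[i] == "public" && distribution[i] == "outside") {
      # a private in-region record must NOT flip the species to "inside"
      emit(labels_for(1), next_bin(), "private", home)
      n_records_planted[i] <- n_records_planted[i] + 1L
    }
  }
  records <- as_barcode_store(bind_rows(rec_env$rows[seq_len(rec_env$n_rows)]))

  truth <- tibble(
    valid_name = valid_name, taxon_group = groups, countries = countries,
    synonym = synonym, barcoded = idx %in% bar_idx,
    availability = availability, distribution = distribution,
    grade = grade, n_records = n_records_planted
  ) |> arrange(.data$valid_name)

  structure(list(
    checklist = checklist,
    synonyms = synonyms,
    records = records,
    truth = truth,
    region = region_spec("focal", cfg$countries),
    config = cfg,
    partner_species = sort(partner_names),
    n_entries_nonbinomial = n_junk,
    n_entries_total = nrow(checklist)
  ), class = "barcode_universe")
}

#' @export
print.barcode_universe <- function(x, ...) {
  cat("<barcode_universe> ", nrow(x$truth), " species, ",
      nrow(x$checklist), " checklist entries, ",
      nrow(x$records), " barcode records (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a universe's fixture files
#'
#' Writes `checklist.tsv`, `synonyms.tsv`, `records.tsv` in the standard
#' dialects plus the truth ledger as `truth.json`.
#'
#' @param universe a [generate_universe()] result.
#' @param dir output directory.
#' @return named character vector of file paths, invisibly.
#' @export
write_universe <- function(universe, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    checklist = file.path(dir, "checklist.tsv"),
    synonyms = file.path(dir, "synonyms.tsv"),
    records = file.path(dir, "records.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_checklist(universe$checklist, paths["checklist"])
  write_synonym_table(universe$synonyms, paths["synonyms"])
  write_barcode_records(universe$records, paths["records"])
  truth <- universe$truth
  truth$countries <- vapply(truth$countries, paste, character(1), collapse = "+")
  jsonlite::write_json(
    list(truth = truth, region = universe$region$member_countries,
         partner_species = universe$partner_species,
         n_entries_nonbinomial = universe$n_entries_nonbinomial,
         n_entries_total = universe$n_entries_total,
         seed = universe$config$seed),
    paths["truth"], dataframe = "rows", auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  invisible(paths)
}

#' Check pipeline outputs against planted truth
#'
#' Compares the per-species availability, distribution and audit grade
#' recovered by [run_gap_analysis()] with the universe's truth ledger.
#'
#' @param universe a [generate_universe()] result (or its `truth` tibble).
#' @param results a [run_gap_analysis()] result on that universe's files.
#' @return discrepancy tibble `valid_name`, `field`, `expected`, `observed`;
#'   zero rows iff every planted label was recovered.
#' @export
truth_check <- function(universe, results) {
  truth <- if (inherits(universe, "barcode_universe")) universe$truth else universe
  s <- results$summaries
  a <- results$audit
  obs <- function(values, names, want) {
    out <- values[match(truth$valid_name, names)]
    out[is.na(out) & !is.na(want)] <- "missing_from_output"
    out
  }
  fields <- list(
    availability = list(exp = truth$availability,
                        obs = obs(s$availability, s$valid_name, truth$availability)),
    distribution = list(exp = truth$distribution,
                        obs = obs(s$distribution, s$valid_name, truth$distribution)),
    grade = list(exp = truth$grade,
                 obs = obs(a$grade, a$valid_name, truth$grade))
  )
  purrr::imap_dfr(fields, function(f, field) {
    bad <- !is.na(f$exp) & (is.na(f$obs) | f$exp != f$obs)
    tibble(valid_name = truth$valid_name[bad], field = field,
           expected = f$exp[bad], observed = f$obs[bad])
  })
}
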