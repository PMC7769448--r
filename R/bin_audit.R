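# BIN-concordance annotation-quality audit for publicly barcoded species.
#
# Grades follow the A/B-to-F scheme used in barcode-library audits:
#   AB  - >= min_barcodes records, one BIN, BIN exclusive to the species
#   C   - >= min_barcodes records, several BINs, all exclusive (split)
#   E*  - >= min_barcodes records, one BIN shared with another species
#   E** - >= min_barcodes records, several BINs, at least one shared
#   D   - fewer than min_barcodes records (data deficient)
#   F   - every record unvouchered or mined from GenBank (inadequate
#         procedure); overrides everything else by default

AUDIT_GRADES <- c("AB", "C", "D", "E*", "E**", "F")

#' Build the BIN -> species index
#'
#' Maps every BIN id to the set of species having at least one public record
#' in it, across the whole store (not just checklist species: a BIN shared
#' with any species signals discordance). Record labels are normalized to
#' valid names through the taxa's search sub-lists; labels matching no taxon
#' keep their own (normalized) label as species identity. Public records
#' without a BIN are excluded and counted in the `n_unbinned` attribute.
#'
#' @param store record-store tibble.
#' @param taxa taxa tibble from [resolve_names()] (may be empty).
#' @return named list `bin_id -> character vector of species`, class
#'   `bin_index`.
#' @export
build_bin_index <- function(store, taxa = NULL) {
  pub <- store[store$visibility == "public", ]
  has_bin <- !is.na(pub$bin_id)
  binned <- pub[has_bin, ]
  species <- norm_species(binned$species_label)
  if (!is.null(taxa) && nrow(taxa) > 0) {
    lookup_keys <- norm_species(unlist(taxa$search_list))
    lookup_vals <- rep(taxa$valid_name, lengths(taxa$search_list))
    hit <- match(species, lookup_keys)
    species[!is.na(hit)] <- lookup_vals[hit[!is.na(hit)]]
  }
  idx <- lapply(split(species, binned$bin_id), function(s) sort(unique(s)))
  structure(idx, class = "bin_index", n_unbinned = sum(!has_bin))
}

#' @export
print.bin_index <- function(x, ...) {
  cat("<bin_index> ", length(x), " BIN(s), ",
      attr(x, "n_unbinned"), " public record(s) without BIN\n", sep = "")
  invisible(x)
}

#' Grade one species' public records
#'
#' Decision procedure, in order: (1) if every record is unvouchered or mined
#' from GenBank, grade `F` (procedural disqualification takes precedence; set
#' `f_precedence = FALSE` to test D first); (2) if the species has fewer than
#' `min_barcodes` records, grade `D`; (3) otherwise grade by BIN topology —
#' one exclusive BIN `AB`, several exclusive BINs `C`, one shared BIN `E*`,
#' several BINs with sharing `E**`. A species with enough records but none
#' carrying a BIN is `"ungradable"` and reported separately. Records without
#' a BIN still count toward the `min_barcodes` threshold. A voucher status of
#' `"unknown"` is treated as vouchered (conservative for F).
#'
#' @param valid_name the species' valid name.
#' @param records tibble of the species' public records.
#' @param index [build_bin_index()] result.
#' @param min_barcodes data-deficiency threshold (default 3: fewer than 3
#'   records is data deficient).
#' @param f_precedence apply the F criterion before the D threshold.
#' @return one-row tibble: `valid_name`, `grade`, `n_barcodes`, `n_bins`,
#'   `shared_bin_species` (semicolon-joined other species sharing a BIN).
#' @export
grade_species <- function(valid_name, records, index, min_barcodes = 3,
                          f_precedence = TRUE) {
  stopifnot(min_barcodes >= 1)
  n <- nrow(records)
  bins <- unique(records$bin_id[!is.na(records$bin_id)])
  others <- sort(unique(unlist(lapply(bins, function(b)
    setdiff(index[[b]], valid_name)))))
  row <- function(grade) tibble(
    valid_name = valid_name, grade = grade, n_barcodes = n,
    n_bins = length(bins),
    shared_bin_species = paste(others, collapse = ";"))

  inadequate <- n > 0 &&
    all(records$voucher_status == "unvouchered" | records$mined_from_genbank)
  if (f_precedence && inadequate) return(row("F"))
  if (n < min_barcodes) return(row("D"))
  if (inadequate) return(row("F"))
  if (length(bins) == 0) return(row("ungradable"))
  shared <- length(others) > 0
  if (length(bins) == 1) {
    return(row(if (shared) "E*" else "AB"))
  }
  row(if (shared) "E**" else "C")
}

#' Audit every publicly barcoded species
#'
#' Runs [grade_species()] over all species whose availability is public,
#' using a BIN index built from the whole store.
#'
#' @param summaries result of [classify_species()].
#' @param taxa taxa tibble from [resolve_names()].
#' @param store record-store tibble.
#' @inheritParams grade_species
#' @return tibble `valid_name`, `taxon_group`, `n_barcodes`, `n_bins`,
#'   `grade`, `shared_bin_species`, one row per audited species.
#' @export
audit_species <- function(summaries, taxa, store, min_barcodes = 3,
                          f_precedence = TRUE) {
  index <- build_bin_index(store, taxa)
  pub_sp <- summaries[summaries$availability == "public", ]
  if (nrow(pub_sp) == 0) {
    return(tibble(valid_name = character(), taxon_group = character(),
                  n_barcodes = integer(), n_bins = integer(),
                  grade = character(), shared_bin_species = character()))
  }
  is_pub <- stats::setNames(store$visibility == "public", store$record_id)
  rows <- purrr::map(seq_len(nrow(pub_sp)), function(i) {
    ids <- pub_sp$matched_record_ids[[i]]
    recs <- store[store$record_id %in% ids[is_pub[ids]], ]
    grade_species(pub_sp$valid_name[i], recs, index,
                  min_barcodes = min_barcodes, f_precedence = f_precedence)
  })
  out <- bind_rows(rows)
  out$taxon_group <- pub_sp$taxon_group
  out[c("valid_name", "taxon_group", "n_barcodes", "n_bins", "grade",
        "shared_bin_species")]
}

#' Grade composition per taxon group
#'
#' Per-group percentage of audited species in each grade, plus the
#' "taxonomic uncertainty" aggregate (C + E* + E**). Percentages within a
#' group are rounded with a largest-remainder scheme so they sum to exactly
#' 100 at the configured precision.
#'
#' @param audit result of [audit_species()].
#' @param digits decimals for the percentage cells.
#' @return tibble `taxon_group`, `grade`, `n_species`, `pct` (long form), with
#'   attribute `"uncertainty"`: a tibble `taxon_group`, `pct_uncertain`.
#' @export
audit_composition <- function(audit, digits = 1) {
  grades <- c(AUDIT_GRADES, "ungradable")
  groups <- sort(unique(audit$taxon_group))
  if (length(groups) == 0) {
    out <- tibble(taxon_group = character(), grade = character(),
                  n_species = integer(), pct = numeric())
    attr(out, "uncertainty") <- tibble(taxon_group = character(),
                                       pct_uncertain = numeric())
    return(out)
  }
  out <- purrr::map_dfr(groups, function(g) {
    sub <- audit[audit$taxon_group == g, ]
    n <- vapply(grades, function(gr) sum(sub$grade == gr), integer(1))
    pct_exact <- if (nrow(sub) > 0) 100 * n / nrow(sub) else n * 0
    pct <- round_to_total(pct_exact, digits = digits)
    tibble(taxon_group = g, grade = grades, n_species = as.integer(unname(n)),
           pct = unname(pct))
  })
  keep <- out$grade != "ungradable" |
    out$n_species > 0 # drop the ungradable row where it is empty
  out <- out[keep, ]
  unc <- out |>
    filter(.data$grade %in% c("C", "E*", "E**")) |>
    group_by(.data$taxon_group) |>
    summarise(pct_uncertain = sum(.data$pct), .groups = "drop")
  attr(out, "uncertainty") <- unc
  out
}
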