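# Independent brute-force re-implementations used as oracles. Deliberately
# written as plain double loops over (taxon, record) pairs, with no shared
# code with the package internals beyond trivial string lower-casing.

ocase <- function(x) tolower(trimws(x))

# availability/distribution per taxon by direct enumeration
oracle_classify <- function(taxa, store, region_countries) {
  res <- list()
  for (i in seq_len(nrow(taxa))) {
    names_i <- ocase(taxa$search_list[[i]])
    ids <- character(0)
    n_pub <- 0L
    any_inside_public <- FALSE
    for (j in seq_len(nrow(store))) {
      if (ocase(store$species_label[j]) %in% names_i) {
        ids <- c(ids, store$record_id[j])
        if (store$visibility[j] == "public") {
          n_pub <- n_pub + 1L
          if (!is.na(store$country[j]) &&
              ocase(store$country[j]) %in% ocase(region_countries)) {
            any_inside_public <- TRUE
          }
        }
      }
    }
    avail <- if (length(ids) == 0) "none"
      else if (n_pub >= 1) "public" else "private_only"
    dist <- if (avail != "public") "not_applicable"
      else if (any_inside_public) "inside" else "outside"
    res[[i]] <- data.frame(valid_name = taxa$valid_name[i],
                           n_records = length(ids), n_public = n_pub,
                           availability = avail, distribution = dist,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# the six audit criteria, straight from their textual definition
oracle_grade <- function(valid_name, store, taxa, min_barcodes = 3) {
  # valid name of any public record's label, via the taxa search lists
  label_owner <- function(label) {
    for (i in seq_len(nrow(taxa))) {
      if (ocase(label) %in% ocase(taxa$search_list[[i]])) {
        return(taxa$valid_name[i])
      }
    }
    paste0(toupper(substr(ocase(label), 1, 1)), substring(ocase(label), 2))
  }
  pub <- store[store$visibility == "public", ]
  mine <- pub[vapply(pub$species_label, function(l)
    identical(label_owner(l), valid_name), logical(1)), ]
  n <- nrow(mine)
  if (n == 0) return(NA_character_)
  if (all(mine$voucher_status == "unvouchered" | mine$mined_from_genbank)) {
    return("F")
  }
  if (n < min_barcodes) return("D")
  bins <- unique(mine$bin_id[!is.na(mine$bin_id)])
  if (length(bins) == 0) return("ungradable")
  shared <- FALSE
  for (b in bins) {
    in_bin <- pub[!is.na(pub$bin_id) & pub$bin_id == b, ]
    owners <- unique(vapply(in_bin$species_label, label_owner, character(1)))
    if (length(setdiff(owners, valid_name)) > 0) shared <- TRUE
  }
  if (length(bins) == 1 && !shared) return("AB")
  if (length(bins) > 1 && !shared) return("C")
  if (length(bins) == 1) return("E*")
  "E**"
}

# exclusive 2^k bucket tally by per-species membership vectors
oracle_shared <- function(country_sets) {
  countries <- names(country_sets)
  species <- unique(unlist(country_sets))
  tally <- new.env()
  for (sp in species) {
    memb <- countries[vapply(countries, function(cc) sp %in% country_sets[[cc]],
                             logical(1))]
    key <- paste(sort(memb), collapse = "+")
    tally[[key]] <- (tally[[key]] %||% 0L) + 1L
  }
  out <- data.frame(countries = ls(tally), stringsAsFactors = FALSE)
  out$n_species <- vapply(out$countries, function(k) tally[[k]], integer(1))
  out
}
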