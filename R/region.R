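#' Define a focal region
#'
#' A region is a named set of member countries, optionally backed by a
#' bounding polygon used only when a record carries coordinates but no country
#' field. The polygon is stored closed (first vertex repeated as the last); an
#' open ring is closed automatically.
#'
#' @param name region name, e.g. `"SEP"` for the Southeast Pacific.
#' @param member_countries non-empty character vector of country names.
#'   Matching is case-insensitive after Unicode normalization and trimming.
#' @param bounding_polygon optional two-column matrix or data frame of
#'   `(lat, lon)` vertices.
#' @return an object of class `region_spec`.
#' @examples
#' sep <- region_spec("SEP", c("Colombia", "Ecuador", "Peru", "Chile"))
#' @export
region_spec <- function(name, member_countries, bounding_polygon = NULL) {
  member_countries <- as.character(member_countries)
  if (length(member_countries) == 0 || all(is.na(member_countries))) {
    abort("a region needs at least one member country")
  }
  poly <- NULL
  if (!is.null(bounding_polygon)) {
    poly <- as.matrix(bounding_polygon)
    storage.mode(poly) <- "double"
    if (ncol(poly) != 2 || nrow(poly) < 3 || anyNA(poly)) {
      abort("bounding_polygon must be a complete (lat, lon) matrix with >= 3 vertices")
    }
    if (!all(poly[1, ] == poly[nrow(poly), ])) {
      poly <- rbind(poly, poly[1, ])
    }
    colnames(poly) <- c("lat", "lon")
  }
  structure(
    list(name = as.character(name)[1],
         member_countries = member_countries,
         member_norm = norm_text(member_countries),
         bounding_polygon = poly),
    class = "region_spec"
  )
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec> ", x$name, ": ",
      paste(x$member_countries, collapse = ", "),
      if (is.null(x$bounding_polygon)) "" else
        sprintf(" [polygon, %d vertices]", nrow(x$bounding_polygon) - 1L),
      "\n", sep = "")
  invisible(x)
}

#' Is a record in the region?
#'
#' Country-field precedence: if a record has a country, membership is decided
#' by that country alone (coordinates are never consulted, as coordinate
#' errors are common in barcode repositories). Only when the country is
#' missing and the region has a bounding polygon do coordinates decide, by
#' point-in-polygon. A record with neither country nor usable coordinates is
#' out of region.
#'
#' @param records record-store tibble (any rows with `country`, `lat`, `lon`).
#' @param region a [region_spec()].
#' @return logical vector, one element per record.
#' @export
record_in_region <- function(records, region) {
  stopifnot(inherits(region, "region_spec"))
  n <- nrow(records)
  if (n == 0) return(logical(0))
  has_country <- !is.na(records$country)
  out <- rep(FALSE, n)
  out[has_country] <- norm_text(records$country[has_country]) %in%
    region$member_norm
  if (!is.null(region$bounding_polygon)) {
    fallback <- !has_country & !is.na(records$lat) & !is.na(records$lon)
    if (any(fallback)) {
      pts <- cbind(records$lat[fallback], records$lon[fallback])
      out[fallback] <- mgcv::in.out(region$bounding_polygon, pts)
    }
  }
  out
}
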