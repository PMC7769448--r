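# Canonical text form used for all name/country comparisons:
# Unicode NFC, trimmed, squeezed whitespace, case-folded.
norm_text <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringr::str_squish(x)
  tolower(x)
}

# Species labels keep their capitalisation convention (Genus epithet) but are
# compared case-insensitively after normalization.
norm_species <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringr::str_squish(x)
  out <- tolower(x)
  ok <- !is.na(out) & nchar(out) > 0
  substr(out[ok], 1, 1) <- toupper(substr(out[ok], 1, 1))
  out
}

#' Round half away from zero
#'
#' Percentage cells in coverage tables are rounded half away from zero (so
#' 6.25 -> 6.3 at one decimal), matching common spreadsheet/report rounding
#' rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  # 1e-9 guard absorbs binary representation error (e.g. 6.25 * 10 stored as
  # 62.49999...); far below half a unit in the last printed place.
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Largest-remainder (Hamilton) apportionment: integer counts summing to n,
# proportional to `weights`. Deterministic: ties broken by index order.
quota_counts <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0))
  if (sum(weights) == 0) {
    return(stats::setNames(integer(length(weights)), names(weights)))
  }
  exact <- n * weights / sum(weights)
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# Round a vector of percentages (summing to 100) so the rounded values still
# sum to exactly 100 at `digits` decimals (largest-remainder on the residuals).
round_to_total <- function(pct, digits = 1, total = 100) {
  if (length(pct) == 0) return(pct)
  p <- 10^digits
  units <- quota_counts(round(total * p), pct)
  units / p
}

# Treat empty strings and "NA" placeholders from TSV as missing.
blank_to_na <- function(x) {
  if (is.character(x)) x[!is.na(x) & stringr::str_squish(x) == ""] <- NA_character_
  x
}

# sample() without the 1:x surprise when x is a length-1 numeric vector
safe_sample <- function(x, size = length(x), replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Deterministic pseudo-Latin word from a non-negative integer index:
# bijective base-k over a syllable alphabet, so distinct indices give
# distinct words made only of lowercase letters.
latin_word <- function(i) {
  syl <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni",
           "po", "ru", "sa", "te", "vo", "xa", "ze", "mu")
  k <- length(syl)
  vapply(as.integer(i), function(n) {
    n <- n + 1L # bijective numeration, no zero digit
    out <- character(0)
    while (n > 0L) {
      d <- ((n - 1L) %% k) + 1L
      out <- c(syl[d], out)
      n <- (n - d) %/% k
    }
    paste(out, collapse = "")
  }, character(1))
}
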