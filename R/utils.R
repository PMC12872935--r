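#' Parse FAERS-style dates
#'
#' FAERS ASCII extracts carry dates as digit strings: `YYYYMMDD`, with partial
#' dates `YYYYMM` or `YYYY` allowed. Partial dates are padded to the first day
#' (and month) so the result is always a full calendar date; anything else is
#' missing, never an error.
#'
#' @param x character vector of raw date fields.
#' @return a `Date` vector, `NA` where unparseable.
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]+$", x)] <- NA_character_
  n <- nchar(x)
  x[!is.na(x) & n == 4L] <- paste0(x[!is.na(x) & n == 4L], "0101")
  n <- nchar(x)
  x[!is.na(x) & n == 6L] <- paste0(x[!is.na(x) & n == 6L], "01")
  n <- nchar(x)
  x[!is.na(x) & n != 8L] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

#' Round half-up
#'
#' Base `round()` rounds half-to-even; report tables in pharmacovigilance
#' papers use the commercial half-up rule (513/1082 -> 47.4), so descriptive
#' percentages go through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count, rounded half-up to one decimal
#'
#' @param count numerator count(s).
#' @param total denominator.
#' @param digits decimal places (default 1, as report tables print).
#' @return numeric percentage(s) on the 0-100 scale.
#' @export
pct_of <- function(count, total, digits = 1) {
  round_half_up(100 * count / total, digits)
}

# uppercase + trim: the only drug-name normalization applied (no fuzzy match)
normalize_name <- function(x) toupper(trimws(as.character(x)))

# order primary ids "largest first": numeric when all coercible, else lexicographic
primary_id_rank <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) num else xtfrm(as.character(x))
}
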