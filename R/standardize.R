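# Canonicalization of demographic fields prior to key construction.

#' Clean a name string for matching
#'
#' Strips blank spaces, commas, apostrophes, and dashes from a name and
#' lowercases it. A value that is empty after stripping (or was missing to
#' begin with) becomes `NA`.
#'
#' @param raw character vector of raw names.
#' @return character vector of cleaned lowercase tokens, `NA` where nothing
#'   remains.
#' @examples
#' clean_name(c("O'Tieno-Ouma ", "AKINYI", "-- , "))
#' @export
clean_name <- function(raw) {
  out <- as.character(raw)
  out[is_absent(out)] <- NA_character_
  out <- gsub("[ ,'’-]", "", out)
  out <- tolower(out)
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Standardize a year of birth to four digits
#'
#' Accepts dates, 4-digit years, and 2-digit years. Two-digit years are
#' resolved with a pivot: values less than or equal to `pivot` map to the
#' 2000s, others to the 1900s.
#'
#' @param dob_or_year a `Date` vector, or a character/numeric vector of year
#'   tokens.
#' @param pivot two-digit-year pivot (default 30).
#' @return integer vector of 4-digit years.
#' @examples
#' standardize_yob(c("1983", "83", "07"))
#' standardize_yob(as.Date("1990-05-01"))
#' @export
standardize_yob <- function(dob_or_year, pivot = 30) {
  if (inherits(dob_or_year, "Date")) {
    return(as.integer(format(dob_or_year, "%Y")))
  }
  tok <- trimws(as.character(dob_or_year))
  out <- rep(NA_integer_, length(tok))
  absent <- is_absent(tok)
  digits <- grepl("^[0-9]{2}$|^[0-9]{4}$", tok)
  bad <- !absent & !digits
  if (any(bad)) {
    stop("unparseable year token(s): ",
         paste(unique(tok[bad]), collapse = ", "))
  }
  four <- !absent & nchar(tok) == 4L
  two <- !absent & nchar(tok) == 2L
  out[four] <- as.integer(tok[four])
  if (any(two)) {
    yy <- as.integer(tok[two])
    out[two] <- ifelse(yy <= pivot, 2000L + yy, 1900L + yy)
  }
  out
}

#' Normalize a comprehensive care clinic (CCC) number
#'
#' A CCC number is an 11-character code: a 5-digit facility code, a
#' separator, and a 5-digit facility-assigned serial. Recording varies
#' (spaces, slashes, dashes, commas, dropped leading zeros); normalization
#' strips all non-digits, takes the first five digits as the facility code,
#' and zero-pads the remaining digits (at most five, never truncated) to a
#' 5-digit serial.
#'
#' @param raw character vector of raw CCC numbers.
#' @param separator separator used in the canonical text (default `"-"`).
#' @return a data.frame with columns `facility_code`, `serial`,
#'   `canonical_text`, and `invalid_reason`. Absent input yields all-`NA`
#'   rows (absent, not invalid); invalid input yields `NA` codes with a
#'   reason.
#' @examples
#' normalize_ccc(c("12345/678", " 12345 , 00678 ", "1234"))
#' @export
normalize_ccc <- function(raw, separator = "-") {
  raw <- as.character(raw)
  n <- length(raw)
  facility <- serial <- canon <- reason <- rep(NA_character_, n)
  absent <- is_absent(raw)
  digits <- gsub("[^0-9]", "", ifelse(absent, "", raw))
  nd <- nchar(digits)
  too_few <- !absent & nd < 6L
  too_many <- !absent & nd > 10L
  ok <- !absent & !too_few & !too_many
  reason[too_few] <- "too_few_digits"
  reason[too_many] <- "too_many_digits"
  facility[ok] <- substr(digits[ok], 1L, 5L)
  serial[ok] <- sprintf("%05d", as.integer(substring(digits[ok], 6L)))
  canon[ok] <- paste0(facility[ok], separator, serial[ok])
  data.frame(facility_code = facility, serial = serial,
             canonical_text = canon, invalid_reason = reason,
             stringsAsFactors = FALSE)
}

#' Canonicalize gender labels
#'
#' Maps common encodings (`"M"`, `"male"`, `"F"`, `"female"`, ...) to the
#' two admissible values `"male"` and `"female"`. Unrecognized values become
#' `NA` with a warning.
#'
#' @param x character vector of raw gender values.
#' @return character vector with values in `c("male", "female", NA)`.
#' @export
standardize_gender <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is_absent(x)] <- NA_character_
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male", "1")] <- "male"
  out[x %in% c("f", "female", "2")] <- "female"
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown)) {
    warning(sum(unknown), " unrecognized gender value(s) set to NA")
  }
  out
}

# missingness: canonical absent marker covers empty strings, whitespace,
# and common sentinel tokens from field data entry
is_absent <- function(x) {
  x <- as.character(x)
  is.na(x) | toupper(trimws(x)) %in% .missing_tokens
}

# day-first (Kenyan convention) date parsing; dialect is a config key,
# never autodetected. Unparseable or impossible calendar dates -> NA.
parse_dates <- function(x, dayfirst = TRUE) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  todo <- !is_absent(x)
  if (!any(todo)) return(out)
  v <- trimws(x[todo])
  iso <- as.Date(v, format = "%Y-%m-%d")
  fmt1 <- if (dayfirst) "%d/%m/%Y" else "%m/%d/%Y"
  fmt2 <- if (dayfirst) "%d-%m-%Y" else "%m-%d-%Y"
  alt <- as.Date(v, format = fmt1)
  alt2 <- as.Date(v, format = fmt2)
  parsed <- ifelse(!is.na(iso), as.character(iso),
                   ifelse(!is.na(alt), as.character(alt), as.character(alt2)))
  # reject roundtrip-inconsistent dates (e.g. 31/02/2015 silently shifted)
  roundtrip_ok <- !is.na(parsed)
  out[todo] <- as.Date(ifelse(roundtrip_ok, parsed, NA))
  out
}
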