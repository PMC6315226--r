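# Reading, validating, filtering, and profiling case-record tables.
#
# A case is defined minimally by date of diagnosis, age at diagnosis,
# gender, first name, and surname; records flow in as CSV exports from
# heterogeneous registers, adapted through a column-name mapping.

.core_fields <- c("record_id", "source_scenario", "facility_id",
                  "first_name", "middle_name", "surname", "gender",
                  "date_of_birth", "year_of_birth", "age_at_diagnosis",
                  "date_of_diagnosis", "ccc_number")

#' Column-name mapping for case-record CSV files
#'
#' Maps canonical field names to the column names of a particular register
#' export. Fields left at their default map to a column of the same name.
#'
#' @param ... named overrides, e.g. `surname = "last_name"`.
#' @return named character vector (canonical field -> source column).
#' @export
case_schema <- function(...) {
  schema <- setNames(.core_fields, .core_fields)
  dots <- c(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), .core_fields)
    if (length(unknown)) {
      stop("unknown schema field(s): ", paste(unknown, collapse = ", "))
    }
    schema[names(dots)] <- dots
  }
  schema
}

#' Read case records from a CSV file
#'
#' Reads a delimited case-record table, applies the column mapping, and
#' standardizes fields: missingness sentinels become `NA`, names keep their
#' raw form (cleaning happens at key construction), gender is canonicalized
#' to `male`/`female`, dates are parsed with a day-first dialect, and the
#' year of birth is standardized to four digits. Unparseable dates are
#' preserved as absent with a warning; row order is preserved.
#'
#' @param path path to a CSV file (UTF-8, header row required).
#' @param schema a [case_schema()] mapping.
#' @param dayfirst logical; parse ambiguous dates day-first (default TRUE).
#' @param pivot two-digit-year pivot for [standardize_yob()].
#' @return a data.frame of case records, one row per input row. Columns not
#'   named in the schema are carried through unmodified as extra fields.
#' @export
read_cases <- function(path, schema = case_schema(), dayfirst = TRUE,
                       pivot = 30) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  mandatory <- c("first_name", "surname", "gender", "date_of_birth",
                 "date_of_diagnosis")
  missing_cols <- mandatory[!(schema[mandatory] %in% names(raw))]
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(schema[missing_cols], collapse = ", "))
  }
  get_col <- function(field) {
    col <- schema[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  n <- nrow(raw)
  if (n == 0) {
    out <- empty_cases()
    attr(out, "extra_fields") <- character(0)
    return(out)
  }
  rid <- get_col("record_id")
  if (all(is_absent(rid))) rid <- sprintf("row%06d", seq_len(n))
  if (anyDuplicated(rid)) stop("record_id values are not unique")
  dob <- parse_dates(get_col("date_of_birth"), dayfirst)
  n_bad_dob <- sum(!is_absent(get_col("date_of_birth")) & is.na(dob))
  dodx <- parse_dates(get_col("date_of_diagnosis"), dayfirst)
  n_bad_dodx <- sum(!is_absent(get_col("date_of_diagnosis")) & is.na(dodx))
  if (n_bad_dob + n_bad_dodx > 0) {
    warning(n_bad_dob + n_bad_dodx,
            " unparseable date value(s) preserved as absent")
  }
  yob_col <- get_col("year_of_birth")
  yob <- standardize_yob(yob_col, pivot)
  yob[is.na(yob) & !is.na(dob)] <- standardize_yob(dob[is.na(yob) & !is.na(dob)])
  scen <- toupper(gsub("[ -]", "_", trimws(get_col("source_scenario"))))
  scen[is_absent(scen)] <- NA_character_
  scen[scen %in% c("HTSCARE", "HTS_TO_CARE")] <- "HTS_CARE"
  scen[scen %in% c("WITHIN_CARE", "CARE_ONLY")] <- "CARE"
  bad_scen <- !is.na(scen) & !(scen %in% .scenarios)
  if (any(bad_scen)) {
    stop("unknown source_scenario value(s): ",
         paste(unique(scen[bad_scen]), collapse = ", "))
  }
  age_raw <- get_col("age_at_diagnosis")
  age <- suppressWarnings(as.integer(age_raw))
  out <- data.frame(
    record_id = as.character(rid),
    source_scenario = scen,
    facility_id = blank_to_na(get_col("facility_id")),
    first_name = blank_to_na(get_col("first_name")),
    middle_name = blank_to_na(get_col("middle_name")),
    surname = blank_to_na(get_col("surname")),
    gender = standardize_gender(get_col("gender")),
    date_of_birth = dob,
    year_of_birth = yob,
    age_at_diagnosis = age,
    date_of_diagnosis = dodx,
    ccc_number = blank_to_na(get_col("ccc_number")),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(raw), unname(schema))
  for (col in extra) out[[col]] <- blank_to_na(raw[[col]])
  attr(out, "extra_fields") <- extra
  out
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[is_absent(x)] <- NA_character_
  x
}

empty_cases <- function() {
  data.frame(record_id = character(0), source_scenario = character(0),
             facility_id = character(0), first_name = character(0),
             middle_name = character(0), surname = character(0),
             gender = character(0), date_of_birth = as.Date(character(0)),
             year_of_birth = integer(0), age_at_diagnosis = integer(0),
             date_of_diagnosis = as.Date(character(0)),
             ccc_number = character(0), stringsAsFactors = FALSE)
}

#' Write case records to CSV
#'
#' RFC 4180-quoted, UTF-8, dates in ISO format; missing values written as
#' empty fields. A write/read round trip reproduces all standardized
#' fields.
#'
#' @param records a case-record data.frame.
#' @param path output path.
#' @export
write_cases <- function(records, path) {
  out <- records
  for (col in c("date_of_birth", "date_of_diagnosis")) {
    if (col %in% names(out)) out[[col]] <- as.character(out[[col]])
  }
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Exclude records unusable for matching
#'
#' A record is excluded iff its date of diagnosis is absent, or its date of
#' birth (including the year) is absent. The diagnosis-date rule is checked
#' first, so a record missing both carries the diagnosis-date reason and is
#' counted once; kept and excluded partition the input.
#'
#' @param records a case-record data.frame.
#' @return a list with elements `kept` (data.frame) and `excluded`
#'   (data.frame with an `exclusion_reason` column).
#' @export
apply_exclusions <- function(records) {
  no_dodx <- is.na(records$date_of_diagnosis)
  no_dob <- !no_dodx & is.na(records$date_of_birth) & is.na(records$year_of_birth)
  reason <- rep(NA_character_, nrow(records))
  reason[no_dodx] <- "missing_date_of_diagnosis"
  reason[no_dob] <- "missing_date_of_birth"
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- reason[!is.na(reason)]
  else excluded$exclusion_reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], excluded = excluded)
}

#' Profile completeness and uniqueness of matching fields
#'
#' For each requested field: completeness (percent nonmissing), the number
#' of distinct nonmissing standardized values, and the nonmissing
#' denominator. Derived phonetic fields (`soundex_first_name`,
#' `phonetic_middle_name`, `phonetic_surname`) are computed on the fly, so
#' the coarsening effect of phonetic standardization can be read off
#' directly.
#'
#' @param records a case-record data.frame.
#' @param fields character vector of field names; defaults to the fields of
#'   the match process.
#' @return a data.frame of class `field_profile` with columns `field`,
#'   `completeness`, `distinct_count`, `denominator`.
#' @export
profile_fields <- function(records,
                           fields = c("gender", "year_of_birth",
                                      "first_name", "soundex_first_name",
                                      "middle_name", "phonetic_middle_name",
                                      "surname", "phonetic_surname")) {
  n <- nrow(records)
  value_of <- function(field) {
    switch(field,
      soundex_first_name = {
        cl <- clean_name(records$first_name)
        ifelse(is.na(cl), NA_character_, soundex_safe(cl))
      },
      phonetic_middle_name = phonetic_for_matchkey(clean_name(records$middle_name)),
      phonetic_surname = phonetic_for_matchkey(clean_name(records$surname)),
      first_name = clean_name(records$first_name),
      middle_name = clean_name(records$middle_name),
      surname = clean_name(records$surname),
      gender = standardize_gender(records$gender),
      {
        if (!field %in% names(records)) stop("unknown field: ", field)
        as.character(records[[field]])
      })
  }
  rows <- lapply(fields, function(field) {
    v <- value_of(field)
    nonmiss <- sum(!is.na(v))
    data.frame(field = field,
               completeness = if (n == 0) 0 else 100 * nonmiss / n,
               distinct_count = length(unique(v[!is.na(v)])),
               denominator = nonmiss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("field_profile", "data.frame")
  out
}

# soundex over possibly non-alphabetic cleaned tokens: encode the
# alphabetic ones, NA out the rest (profiling must not abort on dirty data)
soundex_safe <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & grepl("^[a-z]+$", x)
  if (any(ok)) out[ok] <- soundex(x[ok])
  out
}

#' @export
print.field_profile <- function(x, ...) {
  cat("Field completeness and uniqueness (n = ",
      max(x$denominator), " records)\n\n", sep = "")
  df <- data.frame(field = x$field,
                   `completeness %` = sprintf("%.1f", x$completeness),
                   distinct = x$distinct_count,
                   `out of` = x$denominator, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
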