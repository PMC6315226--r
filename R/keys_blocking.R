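# Match-string and pseudo-unique-key assembly, and scenario blocking.

#' Build phonetic match keys
#'
#' The match key concatenates, without separators: (1) the first character
#' of gender at birth, (2) the Soundex of the first name (uppercase
#' initial), (3) the secondary double metaphone of the middle name
#' (lowercase; the segment is omitted entirely when the middle name is
#' absent), (4) the secondary double metaphone of the surname (lowercase),
#' and (5) the 4-digit year of birth. Example keys: `"fF465aknannk1983"`,
#' `"fG620ans1994"`.
#'
#' @param records a case-record data.frame.
#' @param metaphone_maxlen maximum metaphone segment length (default 4).
#' @return a data.frame with `record_id`, `key_string`, and the five
#'   component segments (`NA` middle segment where absent).
#' @export
build_match_key <- function(records, metaphone_maxlen = 4L) {
  first <- clean_name(records$first_name)
  middle <- clean_name(records$middle_name)
  sur <- clean_name(records$surname)
  gender <- standardize_gender(records$gender)
  yob <- records$year_of_birth
  for (field in c("gender", "first_name", "surname", "year_of_birth")) {
    vals <- switch(field, gender = gender, first_name = first,
                   surname = sur, year_of_birth = yob)
    if (any(is.na(vals))) {
      bad <- records$record_id[is.na(vals)]
      stop("cannot build match key: missing ", field, " for record(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  seg_gender <- substr(gender, 1, 1)
  seg_soundex <- soundex(first)
  seg_middle <- phonetic_for_matchkey(middle, metaphone_maxlen)
  seg_surname <- phonetic_for_matchkey(sur, metaphone_maxlen)
  seg_year <- sprintf("%04d", yob)
  key <- paste0(seg_gender, seg_soundex,
                ifelse(is.na(seg_middle), "", seg_middle),
                seg_surname, seg_year)
  data.frame(record_id = records$record_id, key_string = key,
             seg_gender = seg_gender, seg_soundex = seg_soundex,
             seg_middle = seg_middle, seg_surname = seg_surname,
             seg_year = seg_year, stringsAsFactors = FALSE)
}

#' Build deterministic pseudo-unique keys
#'
#' Concatenation of the Soundex of the first name, the gender character,
#' the cleaned raw surname (not its phonetic code), and the 4-digit year of
#' birth. Records missing any component get no key (`NA`).
#'
#' @param records a case-record data.frame.
#' @return a data.frame with `record_id` and `pseudo_key`.
#' @export
build_pseudo_key <- function(records) {
  first <- clean_name(records$first_name)
  sur <- clean_name(records$surname)
  gender <- standardize_gender(records$gender)
  yob <- records$year_of_birth
  ok <- !is.na(first) & !is.na(sur) & !is.na(gender) & !is.na(yob)
  key <- rep(NA_character_, nrow(records))
  if (any(ok)) {
    key[ok] <- paste0(soundex(first[ok]), substr(gender[ok], 1, 1), sur[ok],
                      sprintf("%04d", yob[ok]))
  }
  data.frame(record_id = records$record_id, pseudo_key = key,
             stringsAsFactors = FALSE)
}

#' Assign records to blocking scenarios
#'
#' Blocking partitions the dataset so that pairwise comparisons happen only
#' among potentially related records. In `exclusive` mode the three
#' care-cascade scenarios (HTS, HTS-care, within care) each form a block;
#' in `combined` mode HTS and HTS-care form a single block
#' (`HTS_UNION_HTSCARE`) so that cross-scenario pairs become comparable,
#' while CARE stays separate.
#'
#' @param records a case-record data.frame; every record must carry a
#'   `source_scenario`.
#' @param mode `"exclusive"` or `"combined"`.
#' @return character vector of block labels, one per record.
#' @export
assign_blocks <- function(records, mode = c("exclusive", "combined")) {
  mode <- match.arg(mode)
  scen <- records$source_scenario
  bad <- is.na(scen) | !(scen %in% .scenarios)
  if (any(bad)) {
    stop("record(s) with unknown source_scenario: ",
         paste(utils::head(records$record_id[bad], 5), collapse = ", "))
  }
  if (mode == "exclusive") return(scen)
  ifelse(scen %in% c("HTS", "HTS_CARE"), "HTS_UNION_HTSCARE", scen)
}
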