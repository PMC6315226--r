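# Synthetic case-record generator with known duplicate structure: the only
# component of the package holding a random source. Matching itself is
# pure, so ground truth from here drives all evaluation.

#' Packaged name pools
#'
#' Curated illustrative word lists shipped with the package: English-origin
#' first names (the study population's first names are mostly English
#' baptismal names) and Kenyan-style given/family names for middle names
#' and surnames. Pools are config-replaceable.
#'
#' @param which one of `"first"`, `"middle"`, `"surname"`.
#' @return character vector of names (lowercase).
#' @export
name_pool <- function(which = c("first", "middle", "surname")) {
  which <- match.arg(which)
  file <- switch(which,
                 first = "first_names_english.txt",
                 middle = "middle_names_kenyan.txt",
                 surname = "surnames_kenyan.txt")
  path <- system.file("extdata", file, package = "cbsmatch")
  if (!nzchar(path)) stop("name pool not found: ", file)
  tolower(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Population parameters for the synthetic generator
#'
#' Defaults mirror the structure of case-based surveillance register
#' data from western Kenya: scenario
#' mix 33.5% HTS / 9.0% HTS-care / 57.5% within care, middle-name
#' completeness 72%, diagnosis dates within a 6-month window, 124
#' facilities.
#'
#' @param n_records number of base records.
#' @param seed random seed (mandatory for reproducibility).
#' @param scenario_proportions named numeric vector over
#'   `c("HTS", "HTS_CARE", "CARE")`, summing to 1.
#' @param middle_name_completeness probability a record has a middle name.
#' @param yob_range integer range of years of birth (pediatric and adult
#'   cases both occur).
#' @param n_facilities number of facilities.
#' @param diagnosis_window `Date` vector of length 2.
#' @param pool_first,pool_middle,pool_surname name pools.
#' @param min_key_separation distinct generated persons are resampled until
#'   no two match keys reach this Jaro-Winkler similarity (default 0.98, the
#'   acceptance threshold), so that ground truth is well defined: no pair of
#'   different persons is indistinguishable to the matcher.
#' @return an object of class `population_params`.
#' @export
population_params <- function(n_records, seed,
                              scenario_proportions = c(HTS = 0.335,
                                                       HTS_CARE = 0.090,
                                                       CARE = 0.575),
                              middle_name_completeness = 0.72,
                              yob_range = c(1935L, 2005L),
                              n_facilities = 124L,
                              diagnosis_window = as.Date(c("2015-01-01",
                                                           "2015-06-30")),
                              pool_first = name_pool("first"),
                              pool_middle = name_pool("middle"),
                              pool_surname = name_pool("surname"),
                              min_key_separation = 0.98) {
  stopifnot(n_records >= 0, length(seed) == 1, is.finite(seed),
            abs(sum(scenario_proportions) - 1) < 1e-8,
            all(scenario_proportions >= 0),
            identical(sort(names(scenario_proportions)), sort(.scenarios)),
            middle_name_completeness >= 0, middle_name_completeness <= 1,
            length(pool_first) > 0, length(pool_middle) > 0,
            length(pool_surname) > 0, yob_range[1] <= yob_range[2])
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 scenario_proportions = scenario_proportions,
                 middle_name_completeness = middle_name_completeness,
                 yob_range = as.integer(yob_range),
                 n_facilities = as.integer(n_facilities),
                 diagnosis_window = diagnosis_window,
                 pool_first = pool_first, pool_middle = pool_middle,
                 pool_surname = pool_surname,
                 min_key_separation = min_key_separation),
            class = "population_params")
}

title_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substring(x, 2))
}

#' Generate a synthetic base population of case records
#'
#' Draws records with the configured scenario mix, middle-name
#' completeness, name pools, birth and diagnosis dates, and facility
#' assignments; care-bearing records (HTS-care and within care) carry
#' canonical-formattable CCC numbers. Distinct generated persons are
#' guaranteed to differ in both their phonetic match key and their
#' pseudo-unique key (draws indistinguishable from an existing person are
#' resampled), so ground truth is well defined. Fully reproducible from
#' the seed.
#'
#' @param params a [population_params()] object.
#' @return a case-record data.frame.
#' @export
generate_population <- function(params) {
  stopifnot(inherits(params, "population_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_records
  if (n == 0) return(empty_cases())
  scen <- sample(names(p$scenario_proportions), n, replace = TRUE,
                 prob = p$scenario_proportions)
  fac_codes <- sprintf("%05d", sample(10000:99999, p$n_facilities))
  fac_idx <- sample.int(p$n_facilities, n, replace = TRUE)
  gender <- sample(c("male", "female"), n, replace = TRUE)
  d0 <- as.Date(sprintf("%d-01-01", p$yob_range[1]))
  d1 <- as.Date(sprintf("%d-12-31", p$yob_range[2]))
  draw_person <- function(k) {
    list(first = sample(p$pool_first, k, replace = TRUE),
         middle = ifelse(runif(k) < p$middle_name_completeness,
                         sample(p$pool_middle, k, replace = TRUE),
                         NA_character_),
         surname = sample(p$pool_surname, k, replace = TRUE),
         dob = d0 + floor(runif(k) * (as.numeric(d1) - as.numeric(d0) + 1)))
  }
  per <- draw_person(n)
  person_keys <- function(per, gender) {
    yob <- standardize_yob(per$dob)
    df <- data.frame(record_id = as.character(seq_along(gender)),
                     first_name = per$first, middle_name = per$middle,
                     surname = per$surname, gender = gender,
                     year_of_birth = yob, stringsAsFactors = FALSE)
    list(match = build_match_key(df)$key_string,
         pseudo = build_pseudo_key(df)$pseudo_key)
  }
  keys <- person_keys(per, gender)
  for (iter in 1:25) {
    # persons indistinguishable to the matcher (equal pseudo keys, or
    # match keys at/above the separation threshold) are redrawn
    clash <- duplicated(keys$pseudo)
    near <- .score_block_cpp(keys$match, 2L, 0.1, 4L, 0.8, 0.8, 1, 0.5,
                             p$min_key_separation)
    clash[near$j] <- TRUE
    if (!any(clash)) break
    redraw <- draw_person(sum(clash))
    for (f in names(per)) per[[f]][clash] <- redraw[[f]]
    keys <- person_keys(per, gender)
  }
  dob <- per$dob
  yob <- standardize_yob(dob)
  w0 <- as.numeric(p$diagnosis_window[1])
  w1 <- as.numeric(p$diagnosis_window[2])
  dodx <- as.Date(w0 + floor(runif(n) * (w1 - w0 + 1)), origin = "1970-01-01")
  care <- scen %in% c("HTS_CARE", "CARE")
  ccc <- rep(NA_character_, n)
  if (any(care)) {
    serial <- ave(seq_len(n)[care], fac_idx[care], FUN = seq_along)
    ccc[care] <- paste0(fac_codes[fac_idx[care]], "-",
                        sprintf("%05d", serial))
  }
  data.frame(
    record_id = sprintf("C%06d", seq_len(n)),
    source_scenario = scen,
    facility_id = sprintf("F%03d", fac_idx),
    first_name = title_case(per$first),
    middle_name = ifelse(is.na(per$middle), NA_character_,
                         title_case(per$middle)),
    surname = title_case(per$surname),
    gender = gender,
    date_of_birth = dob,
    year_of_birth = yob,
    age_at_diagnosis = as.integer(floor((as.numeric(dodx) - as.numeric(dob)) /
                                          30.44)),
    date_of_diagnosis = dodx,
    ccc_number = ccc,
    stringsAsFactors = FALSE)
}

#' Corruption parameters for duplicate injection
#'
#' Per-duplicate probabilities of the corruption operators applied to raw
#' fields before any cleaning. Typo positions are weighted toward indices
#' beyond the fourth character (recording errors are more likely after the
#' first four characters). Defaults are a mixed-corruption profile anchored
#' to a duplicate rate of about 5%.
#'
#' @param duplicate_rate fraction of base records receiving a duplicate.
#' @param p_typo_substitution,p_typo_transposition,p_typo_deletion,p_typo_insertion
#'   probabilities of one character-level typo of each kind in a name.
#' @param p_reformat probability of punctuation/spacing/case reformatting.
#' @param p_middle_dropout probability the duplicate loses its middle name.
#' @param p_ccc_reformat probability the CCC number is reformatted
#'   (spaces, slashes, commas, dropped leading zeros).
#' @param p_dob_shift_within probability of a birth-date shift within the
#'   12-month age tolerance.
#' @param p_dob_shift_beyond probability of a shift beyond the tolerance.
#' @param p_cross_scenario probability an HTS or HTS-care duplicate is
#'   placed in the other of those two scenarios.
#' @param diag_offset_days range of the diagnosis-date offset for the
#'   duplicate episode.
#' @return an object of class `corruption_params`.
#' @export
corruption_params <- function(duplicate_rate = 0.05,
                              p_typo_substitution = 0.25,
                              p_typo_transposition = 0.25,
                              p_typo_deletion = 0.10,
                              p_typo_insertion = 0.10,
                              p_reformat = 0.40,
                              p_middle_dropout = 0.15,
                              p_ccc_reformat = 0.50,
                              p_dob_shift_within = 0.15,
                              p_dob_shift_beyond = 0.03,
                              p_cross_scenario = 0.05,
                              diag_offset_days = c(7L, 150L)) {
  probs <- c(p_typo_substitution, p_typo_transposition, p_typo_deletion,
             p_typo_insertion, p_reformat, p_middle_dropout, p_ccc_reformat,
             p_dob_shift_within, p_dob_shift_beyond, p_cross_scenario)
  stopifnot(all(probs >= 0 & probs <= 1),
            duplicate_rate >= 0, duplicate_rate < 1,
            p_dob_shift_within + p_dob_shift_beyond <= 1)
  structure(list(duplicate_rate = duplicate_rate,
                 p_typo_substitution = p_typo_substitution,
                 p_typo_transposition = p_typo_transposition,
                 p_typo_deletion = p_typo_deletion,
                 p_typo_insertion = p_typo_insertion,
                 p_reformat = p_reformat,
                 p_middle_dropout = p_middle_dropout,
                 p_ccc_reformat = p_ccc_reformat,
                 p_dob_shift_within = p_dob_shift_within,
                 p_dob_shift_beyond = p_dob_shift_beyond,
                 p_cross_scenario = p_cross_scenario,
                 diag_offset_days = as.integer(diag_offset_days)),
            class = "corruption_params")
}

# typo position: indices after the 4th character carry triple weight
sample_typo_pos <- function(len, insert = FALSE) {
  k <- if (insert) len + 1L else len
  if (k <= 0) return(NA_integer_)
  w <- ifelse(seq_len(k) > 4, 3, 1)
  sample.int(k, 1, prob = w)
}

apply_typo <- function(name, op) {
  ch <- strsplit(name, "", fixed = TRUE)[[1]]
  len <- length(ch)
  if (len == 0) return(name)
  if (op == "substitution") {
    i <- sample_typo_pos(len)
    ch[i] <- sample(setdiff(letters, tolower(ch[i])), 1)
  } else if (op == "transposition") {
    if (len < 2) return(name)
    i <- min(sample_typo_pos(len), len - 1L)
    ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]
  } else if (op == "deletion") {
    if (len < 2) return(name)
    ch <- ch[-sample_typo_pos(len)]
  } else if (op == "insertion") {
    i <- sample_typo_pos(len, insert = TRUE)
    ch <- append(ch, sample(letters, 1), after = i - 1L)
  }
  paste(ch, collapse = "")
}

apply_reformat <- function(name) {
  style <- sample(c("upper", "lower", "apostrophe", "dash", "space"), 1)
  switch(style,
         upper = toupper(name),
         lower = tolower(name),
         apostrophe = sub("^(.)", "\\1'", name),
         dash = if (nchar(name) > 3) {
           paste0(substr(name, 1, 2), "-", substring(name, 3))
         } else paste0(name, "-"),
         space = paste0(" ", name, " "))
}

apply_ccc_reformat <- function(ccc) {
  digits <- gsub("[^0-9]", "", ccc)
  fac <- substr(digits, 1, 5)
  serial <- substring(digits, 6)
  style <- sample(c("slash", "spaces", "comma", "nolead", "plain"), 1)
  switch(style,
         slash = paste0(fac, "/", serial),
         spaces = paste0(" ", fac, " - ", serial, " "),
         comma = paste0(fac, ",", serial),
         nolead = paste0(fac, "-", sub("^0+", "", serial)),
         plain = paste0(fac, serial))
}

#' Corrupt one record into a duplicate
#'
#' Applies the configured corruption operators to a copy of `base` under
#' the current RNG state and returns the duplicate together with a
#' manifest of every operator applied. Year of birth and age at diagnosis
#' are kept consistent with the (possibly shifted) birth date.
#'
#' @param base a 1-row case-record data.frame.
#' @param params a [corruption_params()] object.
#' @param new_id record id for the duplicate.
#' @return list with `record` (1-row data.frame) and `manifest` (character
#'   vector of operator tags).
#' @export
corrupt_record <- function(base, params, new_id = paste0(base$record_id, "d")) {
  stopifnot(nrow(base) == 1, inherits(params, "corruption_params"))
  dup <- base
  dup$record_id <- new_id
  manifest <- character(0)
  name_fields <- c("first_name", "middle_name", "surname")
  present <- name_fields[!is.na(unlist(dup[1, name_fields]))]
  typo_ops <- c(substitution = params$p_typo_substitution,
                transposition = params$p_typo_transposition,
                deletion = params$p_typo_deletion,
                insertion = params$p_typo_insertion)
  for (op in names(typo_ops)) {
    if (runif(1) < typo_ops[[op]]) {
      field <- sample(present, 1)
      dup[[field]] <- apply_typo(dup[[field]], op)
      manifest <- c(manifest, paste0("typo_", op, "(", field, ")"))
    }
  }
  if (runif(1) < params$p_reformat) {
    field <- sample(present, 1)
    dup[[field]] <- apply_reformat(dup[[field]])
    manifest <- c(manifest, paste0("reformat(", field, ")"))
  }
  if (!is.na(dup$middle_name) && runif(1) < params$p_middle_dropout) {
    dup$middle_name <- NA_character_
    manifest <- c(manifest, "middle_dropout")
  }
  if (!is.na(dup$ccc_number) && runif(1) < params$p_ccc_reformat) {
    dup$ccc_number <- apply_ccc_reformat(dup$ccc_number)
    manifest <- c(manifest, "ccc_reformat")
  }
  u <- runif(1)
  if (u < params$p_dob_shift_within) {
    shift <- sample(c(-1, 1), 1) * sample(28:330, 1)   # <= 11 months
    dup$date_of_birth <- dup$date_of_birth + shift
    manifest <- c(manifest, "dob_shift_within")
  } else if (u < params$p_dob_shift_within + params$p_dob_shift_beyond) {
    shift <- sample(c(-1, 1), 1) * sample(390:700, 1)  # 13-23 months
    dup$date_of_birth <- dup$date_of_birth + shift
    manifest <- c(manifest, "dob_shift_beyond")
  }
  dup$year_of_birth <- standardize_yob(dup$date_of_birth)
  if (dup$source_scenario %in% c("HTS", "HTS_CARE") &&
      runif(1) < params$p_cross_scenario) {
    dup$source_scenario <- if (dup$source_scenario == "HTS") "HTS_CARE"
                           else "HTS"
    manifest <- c(manifest, "cross_scenario")
  }
  offset <- sample(params$diag_offset_days[1]:params$diag_offset_days[2], 1)
  dup$date_of_diagnosis <- dup$date_of_diagnosis + offset
  dup$age_at_diagnosis <- as.integer(floor(
    (as.numeric(dup$date_of_diagnosis) - as.numeric(dup$date_of_birth)) /
      30.44))
  list(record = dup, manifest = manifest)
}

#' Inject corrupted duplicates into a base population
#'
#' A `duplicate_rate` fraction of base records (rounded half-up) is
#' duplicated via [corrupt_record()]; the combined dataset is shuffled
#' deterministically and ground truth (true pairs with their corruption
#' manifests) is returned alongside.
#'
#' @param records a base case-record data.frame.
#' @param params a [corruption_params()] object.
#' @param seed random seed.
#' @return list with `records` (base plus duplicates, shuffled) and `truth`
#'   (data.frame: `id_a`, `id_b`, `manifest`).
#' @export
inject_duplicates <- function(records, params, seed) {
  stopifnot(inherits(params, "corruption_params"))
  set.seed(seed)
  n <- nrow(records)
  n_dup <- as.integer(floor(params$duplicate_rate * n + 0.5))
  if (n_dup == 0) {
    return(list(records = records,
                truth = data.frame(id_a = character(0), id_b = character(0),
                                   manifest = character(0),
                                   stringsAsFactors = FALSE)))
  }
  base_idx <- sort(sample.int(n, n_dup))
  dups <- vector("list", n_dup)
  manifests <- character(n_dup)
  for (k in seq_len(n_dup)) {
    res <- corrupt_record(records[base_idx[k], , drop = FALSE], params,
                          new_id = sprintf("D%06d", k))
    dups[[k]] <- res$record
    manifests[k] <- paste(res$manifest, collapse = ";")
  }
  dup_df <- do.call(rbind, dups)
  combined <- rbind(records, dup_df)
  combined <- combined[sample.int(nrow(combined)), , drop = FALSE]
  rownames(combined) <- NULL
  base_ids <- records$record_id[base_idx]
  dup_ids <- dup_df$record_id
  truth <- data.frame(id_a = pmin(base_ids, dup_ids),
                      id_b = pmax(base_ids, dup_ids),
                      manifest = manifests, stringsAsFactors = FALSE)
  truth <- truth[order(truth$id_a, truth$id_b), , drop = FALSE]
  rownames(truth) <- NULL
  list(records = combined, truth = truth)
}
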