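# Matching engine: deterministic and score-based matching within blocks,
# age confirmation, and clustering of accepted pairs.

.score_methods <- c("jaro", "jaro_winkler", "levenshtein",
                    "damerau_levenshtein")
.all_methods <- c("deterministic", .score_methods)

#' Matching configuration
#'
#' @param method one of `"deterministic"`, `"jaro"`, `"jaro_winkler"`,
#'   `"levenshtein"`, `"damerau_levenshtein"`.
#' @param threshold similarity acceptance threshold in `(0, 1]`
#'   (default 0.98).
#' @param age_tolerance_months maximum age difference for confirming a
#'   score-based match (default 12).
#' @param jaro_params a [jaro_params()] object.
#' @param edit_weights an [edit_weights()] object.
#' @param blocking_mode `"exclusive"` or `"combined"`.
#' @param audit_margin near-miss pairs with similarity at least
#'   `threshold - audit_margin` are retained (rejected, with a reason) for
#'   human adjudication (default 0.05).
#' @param metaphone_maxlen maximum metaphone segment length in match keys.
#' @return an object of class `match_config`.
#' @export
match_config <- function(method = "jaro_winkler", threshold = 0.98,
                         age_tolerance_months = 12,
                         jaro_params = cbsmatch::jaro_params(),
                         edit_weights = cbsmatch::edit_weights(),
                         blocking_mode = c("exclusive", "combined"),
                         audit_margin = 0.05, metaphone_maxlen = 4L) {
  method <- match.arg(method, .all_methods)
  blocking_mode <- match.arg(blocking_mode)
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold <= 1,
            is.numeric(age_tolerance_months), age_tolerance_months >= 0,
            is.numeric(audit_margin), audit_margin >= 0,
            inherits(jaro_params, "jaro_params"),
            inherits(edit_weights, "edit_weights"))
  structure(list(method = method, threshold = threshold,
                 age_tolerance_months = age_tolerance_months,
                 jaro_params = jaro_params, edit_weights = edit_weights,
                 blocking_mode = blocking_mode, audit_margin = audit_margin,
                 metaphone_maxlen = as.integer(metaphone_maxlen)),
            class = "match_config")
}

#' @export
print.match_config <- function(x, ...) {
  cat("Match configuration\n")
  cat("  method:             ", x$method, "\n")
  if (x$method != "deterministic") {
    cat("  threshold:          ", x$threshold, "\n")
    cat("  age tolerance:      ", x$age_tolerance_months, "months\n")
  }
  cat("  blocking mode:      ", x$blocking_mode, "\n")
  invisible(x)
}

#' Age difference between two records, in months
#'
#' With full birth dates on both sides, the absolute difference in days
#' divided by 30.44 and rounded half-up; with year-only precision on either
#' side, 12 times the absolute year-of-birth difference.
#'
#' @param dob_a,dob_b `Date` vectors (may be `NA` for year-only precision).
#' @param yob_a,yob_b integer years of birth.
#' @return integer vector of nonnegative month differences.
#' @export
compute_age_diff <- function(dob_a, dob_b, yob_a, yob_b) {
  full <- !is.na(dob_a) & !is.na(dob_b)
  out <- integer(length(yob_a))
  if (any(full)) {
    days <- abs(as.numeric(dob_a[full]) - as.numeric(dob_b[full]))
    out[full] <- as.integer(floor(days / 30.44 + 0.5))
  }
  out[!full] <- 12L * abs(yob_a[!full] - yob_b[!full])
  out
}

empty_pairs <- function() {
  data.frame(id_a = character(0), id_b = character(0), method = character(0),
             block = character(0), similarity = numeric(0),
             age_diff_months = integer(0), accepted = logical(0),
             reject_reason = character(0), stringsAsFactors = FALSE)
}

finalize_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(empty_pairs())
  swap <- pairs$id_a > pairs$id_b
  tmp <- pairs$id_a[swap]
  pairs$id_a[swap] <- pairs$id_b[swap]
  pairs$id_b[swap] <- tmp
  pairs <- pairs[order(pairs$id_a, pairs$id_b), , drop = FALSE]
  rownames(pairs) <- NULL
  class(pairs) <- c("scored_pairs", "data.frame")
  pairs
}

#' Deterministic matching
#'
#' Within each block, pairs of records with equal pseudo-unique keys are
#' accepted. Additionally, among records bearing care data (HTS-care and
#' within-care scenarios), pairs with equal canonical CCC numbers that were
#' not already matched are accepted. Deterministic pairs carry similarity
#' 1; the age comparator is not applied (year-of-birth equality is embedded
#' in the key).
#'
#' @param records a case-record data.frame (post-exclusion).
#' @param config a [match_config()] object (supplies the blocking mode).
#' @return a `scored_pairs` data.frame.
#' @export
deterministic_match <- function(records, config = match_config("deterministic")) {
  blocks <- assign_blocks(records, config$blocking_mode)
  pseudo <- build_pseudo_key(records)$pseudo_key
  ccc <- normalize_ccc(records$ccc_number)$canonical_text
  care <- records$source_scenario %in% c("HTS_CARE", "CARE")
  rows <- list()
  pair_within <- function(idx) {
    # all unordered pairs among idx (record row indices)
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  for (bl in unique(blocks)) {
    in_bl <- which(blocks == bl)
    # pseudo-key equality
    keyed <- in_bl[!is.na(pseudo[in_bl])]
    groups <- split(keyed, pseudo[keyed])
    ped <- do.call(rbind, lapply(groups, pair_within))
    seen <- character(0)
    if (!is.null(ped) && nrow(ped)) {
      seen <- paste(pmin(ped$a, ped$b), pmax(ped$a, ped$b))
    }
    # CCC fallback among care-bearing records
    with_ccc <- in_bl[care[in_bl] & !is.na(ccc[in_bl])]
    cgroups <- split(with_ccc, ccc[with_ccc])
    ccc_pairs <- do.call(rbind, lapply(cgroups, pair_within))
    if (!is.null(ccc_pairs) && nrow(ccc_pairs)) {
      key <- paste(pmin(ccc_pairs$a, ccc_pairs$b),
                   pmax(ccc_pairs$a, ccc_pairs$b))
      ccc_pairs <- ccc_pairs[!(key %in% seen), , drop = FALSE]
    }
    ped <- rbind(ped, ccc_pairs)
    if (is.null(ped) || nrow(ped) == 0) next
    rows[[bl]] <- data.frame(
      id_a = records$record_id[ped$a], id_b = records$record_id[ped$b],
      method = "deterministic", block = bl,
      similarity = 1,
      age_diff_months = compute_age_diff(records$date_of_birth[ped$a],
                                         records$date_of_birth[ped$b],
                                         records$year_of_birth[ped$a],
                                         records$year_of_birth[ped$b]),
      accepted = TRUE, reject_reason = NA_character_,
      stringsAsFactors = FALSE)
  }
  finalize_pairs(do.call(rbind, c(rows, list(empty_pairs()))))
}

#' Score-based matching
#'
#' Every unordered within-block pair is scored on the phonetic match keys
#' with the configured kernel (edit-distance kernels are normalized through
#' [edit_similarity()]). A pair is accepted iff its similarity reaches the
#' threshold AND the age difference is within tolerance. Rejected pairs
#' with similarity at least `threshold - audit_margin` are retained with a
#' reject reason (`BELOW_THRESHOLD` or `AGE_MISMATCH`) for adjudication.
#'
#' @param records a case-record data.frame (post-exclusion).
#' @param config a [match_config()] object with a score-based `method`.
#' @return a `scored_pairs` data.frame.
#' @export
score_match <- function(records, config = match_config()) {
  if (!config$method %in% .score_methods) {
    stop("score_match() needs a score-based method, got ", config$method)
  }
  method_code <- match(config$method, .score_methods)
  blocks <- assign_blocks(records, config$blocking_mode)
  keys <- build_match_key(records, config$metaphone_maxlen)$key_string
  min_sim <- max(0, config$threshold - config$audit_margin)
  jp <- config$jaro_params
  w <- config$edit_weights
  rows <- list()
  for (bl in unique(blocks)) {
    idx <- which(blocks == bl)
    if (length(idx) < 2) next
    hits <- .score_block_cpp(keys[idx], method_code, jp$p, jp$max_prefix,
                             w$w_del, w$w_ins, w$w_sub, w$w_trans, min_sim)
    if (length(hits$i) == 0) next
    a <- idx[hits$i]
    b <- idx[hits$j]
    age <- compute_age_diff(records$date_of_birth[a], records$date_of_birth[b],
                            records$year_of_birth[a], records$year_of_birth[b])
    sim <- hits$similarity
    accepted <- sim >= config$threshold & age <= config$age_tolerance_months
    reason <- rep(NA_character_, length(sim))
    reason[!accepted & sim < config$threshold] <- "BELOW_THRESHOLD"
    reason[!accepted & sim >= config$threshold] <- "AGE_MISMATCH"
    rows[[bl]] <- data.frame(
      id_a = records$record_id[a], id_b = records$record_id[b],
      method = config$method, block = bl, similarity = sim,
      age_diff_months = age, accepted = accepted, reject_reason = reason,
      stringsAsFactors = FALSE)
  }
  finalize_pairs(do.call(rbind, c(rows, list(empty_pairs()))))
}

#' Match records with the configured method
#'
#' Dispatches to [deterministic_match()] or [score_match()].
#'
#' @inheritParams score_match
#' @return a `scored_pairs` data.frame.
#' @export
match_records <- function(records, config = match_config()) {
  if (config$method == "deterministic") deterministic_match(records, config)
  else score_match(records, config)
}

#' Cluster accepted pairs into person groups
#'
#' Connected components of the accepted-pair graph; every matched record
#' lands in exactly one cluster. Unmatched records are not emitted.
#'
#' @param pairs a `scored_pairs` data.frame.
#' @return list of character vectors of record ids (each sorted), ordered
#'   by their smallest member id.
#' @export
cluster_pairs <- function(pairs) {
  acc <- pairs[pairs$accepted, c("id_a", "id_b"), drop = FALSE]
  if (nrow(acc) == 0) return(list())
  g <- igraph::graph_from_data_frame(acc, directed = FALSE)
  comp <- igraph::components(g)
  cl <- unname(split(names(comp$membership), comp$membership))
  cl <- lapply(cl, function(x) sort(unname(x)))
  cl[order(vapply(cl, `[`, character(1), 1))]
}
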