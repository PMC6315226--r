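# Post-match processing: cluster resolution with append merge, the
# deduplicated dataset, the master patient index, and yield reporting.

# fields eligible for append merging (extra columns are merged too)
merge_fields <- function(records) {
  setdiff(names(records), c("record_id", "date_of_diagnosis"))
}

#' Resolve a duplicate cluster to one retained record
#'
#' The record with the earliest date of diagnosis is retained (ties broken
#' by most nonmissing fields, then lowest record id). Every field absent in
#' the retained record is overwritten with the first nonmissing value among
#' the other members, ordered by diagnosis date; nonmissing fields are
#' never overwritten. Conflicting nonmissing values are logged, not merged.
#'
#' @param members a case-record data.frame with at least two rows.
#' @return list with `record` (1-row data.frame) and `conflicts`
#'   (data.frame: `retained_id`, `donor_id`, `field`, `retained_value`,
#'   `donor_value`).
#' @export
resolve_cluster <- function(members) {
  stopifnot(nrow(members) >= 2)
  completeness <- rowSums(!is.na(members))
  ord <- order(members$date_of_diagnosis, -completeness, members$record_id)
  members <- members[ord, , drop = FALSE]
  base <- members[1, , drop = FALSE]
  conflicts <- list()
  for (k in seq_len(nrow(members))[-1]) {
    donor <- members[k, , drop = FALSE]
    for (field in merge_fields(members)) {
      bv <- base[[field]]
      dv <- donor[[field]]
      if (is.na(bv) && !is.na(dv)) {
        base[[field]] <- dv
      } else if (!is.na(bv) && !is.na(dv) && !identical(as.character(bv),
                                                        as.character(dv))) {
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          retained_id = base$record_id, donor_id = donor$record_id,
          field = field, retained_value = as.character(bv),
          donor_value = as.character(dv), stringsAsFactors = FALSE)
      }
    }
  }
  list(record = base,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                   else empty_conflicts())
}

empty_conflicts <- function() {
  data.frame(retained_id = character(0), donor_id = character(0),
             field = character(0), retained_value = character(0),
             donor_value = character(0), stringsAsFactors = FALSE)
}

#' Deduplicate a case-record dataset
#'
#' Runs blocking, matching (per the configured method), clustering, and
#' per-cluster resolution, and accounts for the yield per blocking
#' scenario. Records are assumed to have passed [apply_exclusions()].
#'
#' @param records a case-record data.frame.
#' @param config a [match_config()] object.
#' @return an object of class `dedup_result`: a list with `pairs`,
#'   `clusters`, `retained` (the deduplicated dataset), `master_index`
#'   (record_id, cluster_id, retained flag), `per_scenario_counts`,
#'   `conflicts`, `n_input`, `n_duplicates`, `total_unique`, `config`.
#' @export
dedup <- function(records, config = match_config()) {
  stopifnot(nrow(records) == 0 || !anyDuplicated(records$record_id))
  pairs <- match_records(records, config)
  clusters <- cluster_pairs(pairs)
  blocks <- assign_blocks(records, config$blocking_mode)
  names(blocks) <- records$record_id
  rownames(records) <- records$record_id
  resolved <- lapply(clusters, function(ids) {
    resolve_cluster(records[ids, , drop = FALSE])
  })
  retained_rows <- do.call(rbind, c(lapply(resolved, `[[`, "record"),
                                    list(records[0, , drop = FALSE])))
  conflicts <- do.call(rbind, c(lapply(resolved, `[[`, "conflicts"),
                                list(empty_conflicts())))
  in_cluster <- unlist(clusters, use.names = FALSE)
  singletons <- records[!(records$record_id %in% in_cluster), , drop = FALSE]
  retained <- rbind(retained_rows, singletons)
  retained <- retained[order(retained$record_id), , drop = FALSE]
  rownames(retained) <- NULL
  # master patient index: every input record mapped to its cluster
  cluster_id <- if (length(clusters)) {
    sprintf("P%06d", seq_along(clusters))
  } else character(0)
  idx_map <- data.frame(
    record_id = c(in_cluster, singletons$record_id),
    cluster_id = c(rep(cluster_id, lengths(clusters)),
                   singletons$record_id),
    stringsAsFactors = FALSE)
  idx_map$retained <- idx_map$record_id %in% retained$record_id
  idx_map <- idx_map[order(idx_map$record_id), , drop = FALSE]
  rownames(idx_map) <- NULL
  # per-scenario duplicate yield: each cluster lives in one block, and
  # removes (size - 1) duplicates there
  block_labels <- sort(unique(blocks))
  dup_by_block <- setNames(rep(0L, length(block_labels)), block_labels)
  for (ids in clusters) {
    bl <- blocks[[ids[1]]]
    dup_by_block[bl] <- dup_by_block[bl] + length(ids) - 1L
  }
  scen_n <- table(factor(blocks, levels = block_labels))
  per_scenario <- data.frame(block = block_labels,
                             n = as.integer(scen_n),
                             matches = as.integer(dup_by_block),
                             stringsAsFactors = FALSE)
  n_dup <- sum(lengths(clusters) - 1L)
  structure(list(pairs = pairs, clusters = clusters, retained = retained,
                 master_index = idx_map, per_scenario_counts = per_scenario,
                 conflicts = conflicts, n_input = nrow(records),
                 n_duplicates = n_dup,
                 total_unique = nrow(records) - n_dup,
                 config = config),
            class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  cat("Deduplication result (", x$config$method, ", ",
      x$config$blocking_mode, " blocking)\n", sep = "")
  cat("  records in:      ", x$n_input, "\n")
  cat("  duplicates:      ", x$n_duplicates,
      sprintf(" (%.1f%%)", if (x$n_input) 100 * x$n_duplicates / x$n_input else 0),
      "\n", sep = "")
  cat("  unique cases:    ", x$total_unique, "\n")
  cat("  clusters:        ", length(x$clusters), "\n")
  invisible(x)
}

#' @export
summary.dedup_result <- function(object, ...) {
  print(object)
  cat("\nYield by blocking scenario:\n")
  df <- object$per_scenario_counts
  df$pct <- sprintf("%.1f", ifelse(df$n > 0, 100 * df$matches / df$n, 0))
  print(df, row.names = FALSE)
  if (nrow(object$conflicts)) {
    cat("\n", nrow(object$conflicts),
        " merge conflict(s) logged for adjudication\n", sep = "")
  }
  invisible(object)
}

#' Cross-method yield report
#'
#' Tabulates duplicate yield per blocking scenario for several
#' deduplication runs over the same input, in the shape used for
#' surveillance reporting: one row per scenario plus an `All` row (the
#' column sum over scenarios) and a `Unique` row (input total minus
#' `All`); cells carry counts with percentages of the scenario size.
#'
#' @param results named list of `dedup_result` objects computed on the same
#'   input records.
#' @return an object of class `yield_report` with `counts` and `formatted`
#'   matrices.
#' @export
yield_report <- function(results) {
  stopifnot(length(results) >= 1, all(vapply(results, inherits, logical(1),
                                             "dedup_result")))
  n_input <- unique(vapply(results, `[[`, numeric(1), "n_input"))
  if (length(n_input) != 1) {
    stop("all results must be computed on the same input (sizes differ)")
  }
  methods <- names(results) %||% vapply(results, function(r) r$config$method,
                                        character(1))
  blocks <- sort(unique(unlist(lapply(results, function(r)
    r$per_scenario_counts$block))))
  counts <- matrix(0L, nrow = length(blocks) + 2, ncol = length(results),
                   dimnames = list(c(blocks, "All", "Unique"), methods))
  denom <- matrix(n_input, nrow = nrow(counts), ncol = ncol(counts),
                  dimnames = dimnames(counts))
  for (k in seq_along(results)) {
    ps <- results[[k]]$per_scenario_counts
    counts[ps$block, k] <- ps$matches
    denom[ps$block, k] <- ps$n
    counts["All", k] <- sum(ps$matches)
    counts["Unique", k] <- n_input - sum(ps$matches)
  }
  formatted <- matrix(sprintf("%d (%.1f)", counts,
                              ifelse(denom > 0, 100 * counts / denom, 0)),
                      nrow = nrow(counts), dimnames = dimnames(counts))
  structure(list(counts = counts, denominators = denom,
                 formatted = formatted, n_input = n_input),
            class = "yield_report")
}

#' @export
print.yield_report <- function(x, ...) {
  cat("Deduplication yield by scenario and method (N = ", x$n_input,
      ")\n\n", sep = "")
  print(as.data.frame(x$formatted), right = TRUE)
  invisible(x)
}

#' Write a yield report to CSV
#'
#' @param report a `yield_report` object.
#' @param path output CSV path.
#' @export
write_yield_report <- function(report, path) {
  df <- data.frame(scenario = rownames(report$formatted), report$formatted,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
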