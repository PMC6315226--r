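# End-to-end pipeline: read or generate -> exclusions -> keys -> blocks ->
# match -> cluster -> resolve -> report (-> evaluate when truth exists),
# with a machine-readable run manifest.

log_msg <- function(...) message("[cbsmatch] ", ...)

#' Run the full deduplication pipeline
#'
#' Orchestrates the seven-step matching procedure over one configuration:
#' select the data source (a CSV file or a synthetic generation spec),
#' prepare and standardize the data, build match strings, create blocks,
#' run the matching algorithm(s), merge into a deduplicated dataset with a
#' master patient index, and write reports for adjudication. All artifacts
#' land in `output_dir` together with a JSON run manifest; stage counts
#' are logged to standard error. Partial outputs are removed on failure.
#'
#' @param config a named list, or the path to a YAML file, with keys:
#'   `input` (CSV path) or `generate` (list: `n_records`, `seed`, and
#'   optionally `duplicate_rate` plus other [corruption_params()] /
#'   [population_params()] fields), `truth` (optional CSV of true pairs),
#'   `methods` (default: all five), `blocking_mode`, `threshold`,
#'   `age_tolerance_months`, `audit_margin`, `jaro_p`, `max_prefix`,
#'   `w_del`, `w_ins`, `w_sub`, `w_trans`, `dayfirst`, `pivot`,
#'   `output_dir` (required).
#' @return invisibly, a list with the per-method `dedup_result` objects,
#'   the yield report, and any evaluation metrics.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config must name an output_dir")
  if (is.null(config$input) && is.null(config$generate)) {
    stop("config must name an input file or a generation spec")
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE, na = "")
    written <<- c(written, path)
    path
  }
  methods <- config$methods %||% .all_methods
  tryCatch({
    truth <- NULL
    if (!is.null(config$input)) {
      log_msg("reading cases from ", config$input)
      records <- read_cases(config$input,
                            dayfirst = config$dayfirst %||% TRUE,
                            pivot = config$pivot %||% 30)
      if (!is.null(config$truth)) {
        truth <- read.csv(config$truth, colClasses = "character",
                          stringsAsFactors = FALSE)
      }
    } else {
      g <- config$generate
      log_msg("generating synthetic population (n = ", g$n_records,
              ", seed = ", g$seed, ")")
      pop <- generate_population(population_params(
        n_records = g$n_records, seed = g$seed,
        middle_name_completeness = g$middle_name_completeness %||% 0.72))
      cp_args <- g[intersect(names(g), names(formals(corruption_params)))]
      injected <- inject_duplicates(pop, do.call(corruption_params, cp_args),
                                    seed = g$seed + 1)
      records <- injected$records
      truth <- injected$truth
      emit(records, "synthetic_cases.csv")
      emit(truth, "synthetic_truth.csv")
    }
    log_msg("records in: ", nrow(records))
    excl <- apply_exclusions(records)
    log_msg("excluded: ", nrow(excl$excluded), "; kept: ", nrow(excl$kept))
    stopifnot(nrow(excl$kept) + nrow(excl$excluded) == nrow(records))
    emit(excl$excluded, "excluded_records.csv")
    kept <- excl$kept
    keys <- build_match_key(kept)
    pseudo <- build_pseudo_key(kept)
    emit(merge(keys[, c("record_id", "key_string")], pseudo,
               by = "record_id"), "keys.csv")
    results <- list()
    for (m in methods) {
      cfg <- match_config(
        method = m,
        threshold = config$threshold %||% 0.98,
        age_tolerance_months = config$age_tolerance_months %||% 12,
        jaro_params = jaro_params(p = config$jaro_p %||% 0.1,
                                  max_prefix = config$max_prefix %||% 4L),
        edit_weights = edit_weights(w_del = config$w_del %||% 0.8,
                                    w_ins = config$w_ins %||% 0.8,
                                    w_sub = config$w_sub %||% 1,
                                    w_trans = config$w_trans %||% 0.5),
        blocking_mode = config$blocking_mode %||% "exclusive",
        audit_margin = config$audit_margin %||% 0.05)
      log_msg("matching with ", m)
      res <- dedup(kept, cfg)
      log_msg("  duplicates: ", res$n_duplicates, "; unique: ",
              res$total_unique)
      results[[m]] <- res
      out <- res$pairs
      out$similarity <- sprintf("%.6f", out$similarity)
      emit(out, paste0("pairs_", m, ".csv"))
      emit(res$master_index, paste0("master_index_", m, ".csv"))
      write_cases(res$retained, file.path(out_dir,
                                          paste0("deduplicated_", m, ".csv")))
      written <- c(written, file.path(out_dir,
                                      paste0("deduplicated_", m, ".csv")))
      emit(res$conflicts, paste0("conflicts_", m, ".csv"))
    }
    report <- yield_report(results)
    write_yield_report(report, file.path(out_dir, "yield_report.csv"))
    written <- c(written, file.path(out_dir, "yield_report.csv"))
    txt <- file.path(out_dir, "yield_report.txt")
    capture <- utils::capture.output(print(report))
    writeLines(capture, txt)
    written <- c(written, txt)
    metrics <- NULL
    if (!is.null(truth) && nrow(truth)) {
      metrics <- lapply(results, function(r)
        evaluate_matches(r$pairs, truth, kept))
      mjson <- file.path(out_dir, "metrics.json")
      jsonlite::write_json(lapply(metrics, function(m)
        m[c("true_positives", "false_positives", "false_negatives",
            "precision", "recall", "f1")]),
        mjson, auto_unbox = TRUE, digits = NA)
      written <- c(written, mjson)
      for (m in names(metrics)) {
        log_msg(sprintf("%s: precision %.4f recall %.4f", m,
                        metrics[[m]]$precision, metrics[[m]]$recall))
      }
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("cbsmatch")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config[setdiff(names(config), "output_dir")],
      n_records = nrow(records), n_excluded = nrow(excl$excluded),
      methods = methods,
      duplicates = lapply(results, `[[`, "n_duplicates"))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(results = results, report = report, metrics = metrics,
                   records = records, kept = kept, truth = truth))
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at: ", conditionMessage(e), call. = FALSE)
  })
}
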