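# Precision/recall evaluation against synthetic ground truth. Field
# register data rarely come with a gold standard; the synthetic
# generator supplies one.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Evaluate accepted pairs against ground truth
#'
#' Pairwise comparison on unordered record-id pairs: true positives are
#' accepted pairs present in the truth set, false positives are accepted
#' pairs absent from it, false negatives are truth pairs not accepted.
#' Precision is 1 when nothing was accepted and recall is 1 when the truth
#' set is empty (vacuous conventions).
#'
#' @param pairs a `scored_pairs` data.frame (only `accepted` rows count).
#' @param truth a data.frame with columns `id_a`, `id_b`.
#' @param records optional case-record data.frame; when given, truth ids
#'   are validated against it.
#' @return an object of class `eval_metrics`: counts, `precision`,
#'   `recall`, `f1`, and a per-block breakdown of the accepted pairs.
#' @export
evaluate_matches <- function(pairs, truth, records = NULL) {
  if (!is.null(records)) {
    foreign <- setdiff(c(truth$id_a, truth$id_b), records$record_id)
    if (length(foreign)) {
      stop("truth references unknown record id(s): ",
           paste(utils::head(foreign, 5), collapse = ", "))
    }
  }
  acc <- pairs[pairs$accepted, , drop = FALSE]
  akeys <- unique(pair_key(acc$id_a, acc$id_b))
  tkeys <- unique(pair_key(truth$id_a, truth$id_b))
  tp <- sum(akeys %in% tkeys)
  fp <- length(akeys) - tp
  fn <- length(tkeys) - tp
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  by_block <- NULL
  if (nrow(acc)) {
    key <- pair_key(acc$id_a, acc$id_b)
    by_block <- do.call(rbind, lapply(split(key, acc$block), function(k) {
      k <- unique(k)
      tpb <- sum(k %in% tkeys)
      data.frame(accepted = length(k), true_positive = tpb,
                 false_positive = length(k) - tpb)
    }))
    by_block <- data.frame(block = rownames(by_block), by_block,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(true_positives = tp, false_positives = fp,
                 false_negatives = fn, precision = precision,
                 recall = recall, f1 = f1, by_block = by_block),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat("Pairwise evaluation against ground truth\n")
  cat(sprintf("  TP %d, FP %d, FN %d\n", x$true_positives,
              x$false_positives, x$false_negatives))
  cat(sprintf("  precision %.4f, recall %.4f, F1 %.4f\n", x$precision,
              x$recall, x$f1))
  if (!is.null(x$by_block)) {
    cat("  accepted pairs by block:\n")
    print(x$by_block, row.names = FALSE)
  }
  invisible(x)
}
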