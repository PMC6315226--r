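# String similarity and weighted edit-distance kernels. The heavy lifting
# is in C++ (src/kernels.cpp); these wrappers recycle arguments and carry
# the parameter objects.

#' Edit-operation weights
#'
#' Costs for the weighted Levenshtein and Damerau-Levenshtein distances.
#' Defaults reflect the error profile of hand-keyed demographic data:
#' deletion 0.8, insertion 0.8, substitution 1, transposition 0.5
#' (transposition applies to the Damerau variant only).
#'
#' @param w_del,w_ins,w_sub,w_trans nonnegative costs.
#' @return an object of class `edit_weights`.
#' @export
edit_weights <- function(w_del = 0.8, w_ins = 0.8, w_sub = 1, w_trans = 0.5) {
  w <- list(w_del = w_del, w_ins = w_ins, w_sub = w_sub, w_trans = w_trans)
  if (any(vapply(w, function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1)))) {
    stop("edit weights must be single nonnegative numbers")
  }
  structure(w, class = "edit_weights")
}

#' Jaro-Winkler parameters
#'
#' @param p prefix scaling penalty factor in `[0, 0.25]` (default 0.1).
#' @param max_prefix maximum shared-prefix length rewarded, in `0:4`
#'   (default 4).
#' @return an object of class `jaro_params`.
#' @export
jaro_params <- function(p = 0.1, max_prefix = 4L) {
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 0.25) {
    stop("p must be in [0, 0.25]")
  }
  max_prefix <- as.integer(max_prefix)
  if (is.na(max_prefix) || max_prefix < 0L || max_prefix > 4L) {
    stop("max_prefix must be in 0:4")
  }
  structure(list(p = p, max_prefix = max_prefix), class = "jaro_params")
}

recycle2 <- function(s1, s2) {
  n <- max(length(s1), length(s2))
  list(s1 = rep_len(as.character(s1), n), s2 = rep_len(as.character(s2), n))
}

#' Jaro similarity
#'
#' \eqn{d_j = \frac13 (m/|s_1| + m/|s_2| + (m-t)/m)} where `m` is the number
#' of matching characters within the standard window
#' \eqn{\lfloor \max(|s_1|,|s_2|)/2 \rfloor - 1} and `t` is half the number
#' of matched characters in different sequence order. Zero when no
#' characters match; 1 when both strings are empty.
#'
#' @param s1,s2 character vectors (recycled).
#' @return numeric vector of similarities in `[0, 1]`.
#' @examples
#' jaro("martha", "marhta")
#' @export
jaro <- function(s1, s2) {
  z <- recycle2(s1, s2)
  .jaro_cpp(z$s1, z$s2)
}

#' Jaro-Winkler similarity
#'
#' \eqn{d_{jw} = d_j + \ell \, p \, (1 - d_j)} with \eqn{\ell} the length of
#' the common prefix capped at `max_prefix`. The prefix boost reflects that
#' recording errors are more likely after the first four characters.
#'
#' @param s1,s2 character vectors (recycled).
#' @param params a [jaro_params()] object.
#' @return numeric vector of similarities in `[0, 1]`.
#' @examples
#' jaro_winkler("martha", "marhta")
#' @export
jaro_winkler <- function(s1, s2, params = jaro_params()) {
  stopifnot(inherits(params, "jaro_params"))
  z <- recycle2(s1, s2)
  .jaro_winkler_cpp(z$s1, z$s2, params$p, params$max_prefix)
}

#' Weighted Levenshtein edit cost
#'
#' Minimum total cost of deletions, insertions, and substitutions
#' transforming `s1` into `s2`, at the given weights.
#'
#' @param s1,s2 character vectors (recycled).
#' @param weights an [edit_weights()] object.
#' @return numeric vector of nonnegative costs; 0 iff the strings are equal
#'   (for positive weights).
#' @examples
#' weighted_levenshtein("abcd", "abc")
#' @export
weighted_levenshtein <- function(s1, s2, weights = edit_weights()) {
  stopifnot(inherits(weights, "edit_weights"))
  z <- recycle2(s1, s2)
  .wlev_cpp(z$s1, z$s2, weights$w_del, weights$w_ins, weights$w_sub)
}

#' Weighted Damerau-Levenshtein edit cost
#'
#' As [weighted_levenshtein()] plus transposition of two characters at
#' `w_trans`. This is the full (Lowrance-Wagner) variant rather than the
#' restricted optimal-string-alignment one: a transposed pair may be
#' separated by material that is itself deleted or inserted, but each
#' character takes part in at most one transposition.
#'
#' @inheritParams weighted_levenshtein
#' @return numeric vector of nonnegative costs.
#' @examples
#' weighted_damerau_levenshtein("abcd", "abdc")
#' @export
weighted_damerau_levenshtein <- function(s1, s2, weights = edit_weights()) {
  stopifnot(inherits(weights, "edit_weights"))
  z <- recycle2(s1, s2)
  .wdl_cpp(z$s1, z$s2, weights$w_del, weights$w_ins, weights$w_sub,
           weights$w_trans)
}

#' Normalize an edit cost to a similarity
#'
#' `1 - cost / max(|s1|, |s2|)`, floored at 0; 1 when both strings are
#' empty. This keeps the 98% acceptance threshold meaningful for match keys
#' of roughly 12-18 characters.
#'
#' @param s1,s2 the strings the cost was computed on (recycled).
#' @param cost nonnegative edit cost.
#' @return numeric vector of similarities in `[0, 1]`.
#' @export
edit_similarity <- function(s1, s2, cost) {
  z <- recycle2(s1, s2)
  mx <- pmax(nchar(z$s1), nchar(z$s2))
  out <- ifelse(mx == 0, 1, pmax(0, 1 - cost / pmax(mx, 1)))
  as.numeric(out)
}
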