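# Phonetic encoders: American Soundex and double metaphone.
#
# First names in the study population are mostly English baptismal names,
# for which Soundex is adequate; middle names and surnames are Kenyan
# native names, for which the secondary double metaphone has better
# discriminatory power.

.soundex_digit <- local({
  map <- rep(NA_character_, 26)
  names(map) <- letters
  map[c("b", "f", "p", "v")] <- "1"
  map[c("c", "g", "j", "k", "q", "s", "x", "z")] <- "2"
  map[c("d", "t")] <- "3"
  map["l"] <- "4"
  map[c("m", "n")] <- "5"
  map["r"] <- "6"
  map[c("a", "e", "i", "o", "u", "y")] <- "0"   # vowels reset the run
  map[c("h", "w")] <- "."                       # skipped, do not reset
  map
})

#' American Soundex code
#'
#' Letter-plus-three-digits phonetic code: the first letter is retained
#' (uppercased), remaining consonants map to digit classes, vowels reset
#' runs of equal digits, and `h`/`w` are transparent (equal digit classes
#' collapse across them).
#'
#' @param name character vector of cleaned, alphabetic name tokens.
#' @return character vector of 4-character codes (e.g. `"R163"`).
#' @examples
#' soundex(c("robert", "rupert", "florence", "grace"))
#' @export
soundex <- function(name) {
  name <- tolower(as.character(name))
  if (any(is.na(name) | !nzchar(name))) {
    stop("soundex() requires nonempty input")
  }
  if (any(grepl("[^a-z]", name))) {
    bad <- unique(name[grepl("[^a-z]", name)])
    stop("soundex() input must be alphabetic after cleaning: ",
         paste(bad, collapse = ", "))
  }
  vapply(name, function(x) {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    codes <- .soundex_digit[ch]
    out <- character(0)
    prev <- codes[1]
    if (prev == ".") prev <- "0"
    for (k in seq_along(ch)[-1]) {
      cd <- codes[k]
      if (cd == ".") next          # h/w: transparent
      if (cd == "0") { prev <- "0"; next }
      if (cd != prev) out <- c(out, cd)
      prev <- cd
    }
    paste0(toupper(substr(x, 1, 1)),
           substr(paste0(paste(out, collapse = ""), "000"), 1, 3))
  }, character(1), USE.NAMES = FALSE)
}

#' Double metaphone codes
#'
#' Primary and secondary phonetic codes per the published double metaphone
#' rule set. For names that trigger no ambiguous-pronunciation rule the
#' secondary code equals the primary.
#'
#' @param name character vector of cleaned name tokens (nonempty).
#' @param maxlen maximum code length (default 4, the published default).
#' @return a data.frame with columns `primary`, `secondary`, and
#'   `alternate` (whether any dual-pronunciation rule fired).
#' @examples
#' double_metaphone(c("smith", "otieno", "anyango"))
#' @export
double_metaphone <- function(name, maxlen = 4L) {
  name <- as.character(name)
  if (any(is.na(name) | !nzchar(name))) {
    stop("double_metaphone() requires nonempty input")
  }
  res <- .dmetaphone_cpp(name, as.integer(maxlen))
  data.frame(primary = res$primary, secondary = res$secondary,
             alternate = res$alternate, stringsAsFactors = FALSE)
}

#' Phonetic code segment for match-key assembly
#'
#' Lowercased secondary double metaphone of a name; falls back to the
#' primary code when the secondary is empty. Absent names stay absent (the
#' match key is then built without this segment).
#'
#' @param name character vector of cleaned name tokens, `NA` allowed.
#' @param maxlen maximum metaphone code length.
#' @return lowercase code strings, `NA` where the input was absent.
#' @examples
#' phonetic_for_matchkey(c("smith", NA, "anyango"))
#' @export
phonetic_for_matchkey <- function(name, maxlen = 4L) {
  out <- rep(NA_character_, length(name))
  ok <- !is.na(name) & nzchar(name)
  if (any(ok)) {
    dm <- double_metaphone(name[ok], maxlen)
    code <- ifelse(nzchar(dm$secondary), dm$secondary, dm$primary)
    out[ok] <- tolower(code)
  }
  out
}
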