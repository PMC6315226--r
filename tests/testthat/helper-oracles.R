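# Independent reference implementations used as oracles, plus fixture
# builders. These stay deliberately naive: the point is that they share no
# code path with the package kernels.

# Jaro similarity written directly from the definition (explicit loops,
# greedy window matching).
jaro_reference <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(av)
  lb <- length(bv)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  win <- max(floor(max(la, lb) / 2) - 1, 0)
  am <- rep(FALSE, la)
  bm <- rep(FALSE, lb)
  for (i in seq_len(la)) {
    lo <- max(1, i - win)
    hi <- min(lb, i + win)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!bm[j] && av[i] == bv[j]) {
        am[i] <- TRUE
        bm[j] <- TRUE
        break
      }
    }
  }
  m <- sum(am)
  if (m == 0) return(0)
  t <- sum(av[am] != bv[bm]) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

# Minimum edit cost by memoized enumeration of edit scripts (leftmost
# decomposition). With transpositions = TRUE, a transposition pairs av[i]
# with bv[l] and av[k] with bv[j], the characters between being deleted /
# inserted at their usual cost and taking part in no other operation --
# every candidate (k, l) is enumerated, not just the nearest occurrence.
edit_script_oracle <- function(a, b, wd = 0.8, wi = 0.8, ws = 1, wt = 0.5,
                               transpositions = FALSE) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    la <- length(av) - i + 1
    lb <- length(bv) - j + 1
    if (la == 0 && lb == 0) {
      res <- 0
    } else {
      cands <- numeric(0)
      if (la > 0) cands <- c(cands, wd + rec(i + 1, j))
      if (lb > 0) cands <- c(cands, wi + rec(i, j + 1))
      if (la > 0 && lb > 0) {
        cands <- c(cands,
                   (if (av[i] == bv[j]) 0 else ws) + rec(i + 1, j + 1))
      }
      if (transpositions && la >= 2 && lb >= 2) {
        for (k in (i + 1):length(av)) {
          for (l in (j + 1):length(bv)) {
            if (av[i] == bv[l] && av[k] == bv[j]) {
              cands <- c(cands, wt + (k - i - 1) * wd + (l - j - 1) * wi +
                           rec(k + 1, l + 1))
            }
          }
        }
      }
      res <- min(cands)
    }
    memo[[key]] <- res
    res
  }
  rec(1, 1)
}

# all strings over `alphabet` with lengths 0..maxlen
all_strings <- function(alphabet, maxlen) {
  out <- ""
  for (L in seq_len(maxlen)) {
    grid <- expand.grid(rep(list(alphabet), L), stringsAsFactors = FALSE)
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# compact case-record builder for engine/postmatch tests
make_cases <- function(first, surname, gender = "female", yob = 1980L,
                       middle = NA_character_, dob = NULL, dodx = NULL,
                       scenario = "HTS", ccc = NA_character_,
                       facility = "F001", id = NULL) {
  n <- max(length(first), length(surname), length(yob), length(scenario))
  first <- rep_len(first, n)
  surname <- rep_len(surname, n)
  gender <- rep_len(gender, n)
  yob <- rep_len(as.integer(yob), n)
  middle <- rep_len(middle, n)
  scenario <- rep_len(scenario, n)
  ccc <- rep_len(ccc, n)
  facility <- rep_len(facility, n)
  if (is.null(dob)) dob <- as.Date(sprintf("%d-06-15", yob))
  if (is.null(dodx)) dodx <- rep(as.Date("2015-03-01"), n)
  if (is.null(id)) id <- sprintf("r%03d", seq_len(n))
  data.frame(record_id = id, source_scenario = scenario,
             facility_id = facility, first_name = first,
             middle_name = middle, surname = surname, gender = gender,
             date_of_birth = rep_len(dob, n), year_of_birth = yob,
             age_at_diagnosis = NA_integer_,
             date_of_diagnosis = rep_len(dodx, n), ccc_number = ccc,
             stringsAsFactors = FALSE)
}

# random key-shaped strings: gender char + soundex-like + lowercase
# phonetic segments + year
rand_keys <- function(n) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("f", "m"), 1),
           sample(LETTERS, 1),
           paste(sample(0:9, 3, replace = TRUE), collapse = ""),
           paste(sample(letters, sample(3:8, 1), replace = TRUE),
                 collapse = ""),
           sample(1940:2005, 1))
  }, character(1))
}

formatting_only_params <- function(duplicate_rate = 0.05) {
  corruption_params(duplicate_rate = duplicate_rate,
                    p_typo_substitution = 0, p_typo_transposition = 0,
                    p_typo_deletion = 0, p_typo_insertion = 0,
                    p_reformat = 1, p_middle_dropout = 0,
                    p_ccc_reformat = 1, p_dob_shift_within = 0,
                    p_dob_shift_beyond = 0, p_cross_scenario = 0)
}
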