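test_that("age difference uses days for full dates, years otherwise", {
  expect_equal(compute_age_diff(as.Date("1983-01-15"), as.Date("1983-01-15"),
                                1983L, 1983L), 0L)
  # 365 days / 30.44 rounds half-up to 12
  expect_equal(compute_age_diff(as.Date("1983-01-15"), as.Date("1984-01-15"),
                                1983L, 1984L), 12L)
  # year-only precision on either side
  expect_equal(compute_age_diff(as.Date(NA), as.Date("1985-03-01"),
                                1983L, 1985L), 24L)
  expect_equal(compute_age_diff(as.Date(NA), as.Date(NA), 1990L, 1990L), 0L)
})

test_that("deterministic matching pairs equal pseudo-keys within blocks", {
  rec <- make_cases(first = c("Grace", "grace", "Grace"),
                    surname = c("Anyango", "Anyango", "Anyango"),
                    yob = 1994L,
                    scenario = c("HTS", "HTS", "CARE"))
  pairs <- deterministic_match(rec, match_config("deterministic"))
  # same block pair found; cross-block pair invisible in exclusive mode
  expect_equal(nrow(pairs), 1)
  expect_equal(c(pairs$id_a, pairs$id_b), c("r001", "r002"))
  expect_equal(pairs$similarity, 1)
  expect_true(pairs$accepted)
})

test_that("CCC fallback catches care records the pseudo-key misses", {
  rec <- make_cases(first = c("Grace", "Grace"),
                    surname = c("Anyango", "Anyengo"),  # typo breaks pseudo-key
                    yob = 1994L, scenario = "CARE",
                    ccc = c("12345-00007", "12345/7"))
  pairs <- deterministic_match(rec, match_config("deterministic"))
  expect_equal(nrow(pairs), 1)
  expect_true(pairs$accepted)
  # the same typo without care data stays unmatched deterministically
  rec_hts <- rec
  rec_hts$source_scenario <- "HTS"
  rec_hts$ccc_number <- NA_character_
  expect_equal(nrow(deterministic_match(rec_hts,
                                        match_config("deterministic"))), 0)
})

test_that("score matching accepts identical keys and confirms age", {
  rec <- make_cases(first = c("Grace", "Grace"), surname = "Anyiso",
                    yob = 1994L, dob = as.Date(c("1994-02-01", "1994-05-01")))
  for (m in c("jaro", "jaro_winkler", "levenshtein", "damerau_levenshtein")) {
    pairs <- score_match(rec, match_config(m))
    expect_equal(nrow(pairs), 1)
    expect_equal(pairs$similarity, 1)
    expect_true(pairs$accepted)
  }
})

test_that("identical keys with discordant birth dates hit the age gate", {
  # same recorded year of birth (hence identical keys) but birth dates
  # 20 months apart: the comparator rejects what the key accepts
  rec <- make_cases(first = c("Grace", "Grace"), surname = "Anyiso",
                    yob = 1994L, dob = as.Date(c("1994-01-01", "1995-09-01")))
  pairs <- score_match(rec, match_config("jaro_winkler"))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$age_diff_months, 20L)
  expect_false(pairs$accepted)
  expect_equal(pairs$reject_reason, "AGE_MISMATCH")
})

test_that("near-miss pairs are retained below threshold for adjudication", {
  rec <- make_cases(first = c("Florence", "Florence"),
                    middle = c("Akinyi", "Akinyi"),
                    surname = c("Anyango", "Anyango"),
                    yob = c(1983L, 1984L),
                    dob = as.Date(c("1983-06-15", "1984-06-15")))
  # keys differ in one year digit: jw = 0.975 (hand-computed), below the
  # 0.98 threshold but inside the 0.05 audit margin
  pairs <- score_match(rec, match_config("jaro_winkler"))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$similarity, 0.975, tolerance = 1e-9)
  expect_false(pairs$accepted)
  expect_equal(pairs$reject_reason, "BELOW_THRESHOLD")
  # tighter audit margin drops the pair from the output entirely
  tight <- score_match(rec, match_config("jaro_winkler", audit_margin = 0))
  expect_equal(nrow(tight), 0)
})

test_that("threshold monotonicity: raising it never adds accepted pairs", {
  pop <- generate_population(population_params(n_records = 400, seed = 51))
  inj <- inject_duplicates(pop, corruption_params(duplicate_rate = 0.08),
                           seed = 52)
  prev <- NULL
  for (thr in c(1.00, 0.98, 0.95)) {
    pairs <- score_match(inj$records,
                         match_config("jaro_winkler", threshold = thr))
    acc <- pairs[pairs$accepted, ]
    keyset <- paste(acc$id_a, acc$id_b)
    if (!is.null(prev)) expect_true(all(prev %in% keyset))
    prev <- keyset
  }
})

test_that("jaro-winkler accepts a superset of jaro at equal threshold", {
  pop <- generate_population(population_params(n_records = 400, seed = 53))
  inj <- inject_duplicates(pop, corruption_params(duplicate_rate = 0.08),
                           seed = 54)
  pj <- score_match(inj$records, match_config("jaro"))
  pjw <- score_match(inj$records, match_config("jaro_winkler"))
  kj <- with(pj[pj$accepted, ], paste(id_a, id_b))
  kjw <- with(pjw[pjw$accepted, ], paste(id_a, id_b))
  expect_true(all(kj %in% kjw))
})

test_that("matching is deterministic and pairs are canonically ordered", {
  pop <- generate_population(population_params(n_records = 300, seed = 55))
  inj <- inject_duplicates(pop, corruption_params(), seed = 56)
  p1 <- score_match(inj$records, match_config("jaro_winkler"))
  p2 <- score_match(inj$records, match_config("jaro_winkler"))
  expect_identical(p1, p2)
  expect_true(all(p1$id_a < p1$id_b))
  expect_false(is.unsorted(p1$id_a))
})

test_that("clusters are connected components of accepted pairs", {
  pairs <- data.frame(id_a = c("A", "B", "C"), id_b = c("B", "C", "D"),
                      accepted = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  cl <- cluster_pairs(pairs)
  expect_equal(cl, list(c("A", "B", "C")))
  pairs2 <- data.frame(id_a = c("A", "C"), id_b = c("B", "D"),
                       accepted = TRUE, stringsAsFactors = FALSE)
  expect_equal(cluster_pairs(pairs2), list(c("A", "B"), c("C", "D")))
  expect_equal(cluster_pairs(pairs[0, ]), list())
})
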