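test_that("generation is reproducible and honors the scenario mix", {
  pp <- population_params(n_records = 800, seed = 71)
  a <- generate_population(pp)
  b <- generate_population(pp)
  expect_identical(a, b)
  expect_equal(nrow(a), 800)
  mix <- table(a$source_scenario) / nrow(a)
  expect_equal(unname(mix["HTS"]), 0.335, tolerance = 0.08)
  expect_equal(unname(mix["CARE"]), 0.575, tolerance = 0.08)
  # degenerate mix
  solo <- generate_population(population_params(
    n_records = 50, seed = 72,
    scenario_proportions = c(HTS = 1, HTS_CARE = 0, CARE = 0)))
  expect_true(all(solo$source_scenario == "HTS"))
})

test_that("middle-name completeness lands near its parameter", {
  pop <- generate_population(population_params(n_records = 1000, seed = 73))
  expect_equal(mean(!is.na(pop$middle_name)), 0.72, tolerance = 0.05)
})

test_that("generated records are internally consistent", {
  pop <- generate_population(population_params(n_records = 400, seed = 74))
  expect_false(anyDuplicated(pop$record_id) > 0)
  expect_equal(pop$year_of_birth,
               as.integer(format(pop$date_of_birth, "%Y")))
  care <- pop$source_scenario %in% c("HTS_CARE", "CARE")
  expect_true(all(!is.na(pop$ccc_number[care])))
  expect_true(all(is.na(pop$ccc_number[!care])))
  expect_true(all(grepl("^[0-9]{5}-[0-9]{5}$", pop$ccc_number[care])))
  win <- range(pop$date_of_diagnosis)
  expect_gte(as.numeric(win[1] - as.Date("2015-01-01")), 0)
  expect_lte(as.numeric(win[2] - as.Date("2015-06-30")), 0)
})

test_that("distinct persons are separable by construction", {
  pop <- generate_population(population_params(n_records = 1500, seed = 75))
  keys <- build_match_key(pop)$key_string
  expect_false(anyDuplicated(keys) > 0)
  pk <- build_pseudo_key(pop)$pseudo_key
  expect_false(anyDuplicated(pk[!is.na(pk)]) > 0)
  # no two base persons within the acceptance threshold of each other
  hits <- cbsmatch:::.score_block_cpp(keys, 2L, 0.1, 4L, 0.8, 0.8, 1, 0.5,
                                      0.98)
  expect_length(hits$i, 0)
})

test_that("duplicate injection counts, shuffles, and records truth", {
  pop <- generate_population(population_params(n_records = 1000, seed = 76))
  inj <- inject_duplicates(pop, corruption_params(duplicate_rate = 0.05),
                           seed = 77)
  expect_equal(nrow(inj$records), 1050)
  expect_equal(nrow(inj$truth), 50)
  expect_true(all(inj$truth$id_a < inj$truth$id_b))
  expect_true(all(c(inj$truth$id_a, inj$truth$id_b) %in%
                    inj$records$record_id))
  # reproducibility
  inj2 <- inject_duplicates(pop, corruption_params(duplicate_rate = 0.05),
                            seed = 77)
  expect_identical(inj, inj2)
  # zero rate: nothing happens
  none <- inject_duplicates(pop, corruption_params(duplicate_rate = 0),
                            seed = 78)
  expect_identical(none$records, pop)
  expect_equal(nrow(none$truth), 0)
})

test_that("identity corruption copies every field except the id", {
  pop <- generate_population(population_params(n_records = 20, seed = 79))
  quiet <- corruption_params(duplicate_rate = 0, p_typo_substitution = 0,
                             p_typo_transposition = 0, p_typo_deletion = 0,
                             p_typo_insertion = 0, p_reformat = 0,
                             p_middle_dropout = 0, p_ccc_reformat = 0,
                             p_dob_shift_within = 0, p_dob_shift_beyond = 0,
                             p_cross_scenario = 0,
                             diag_offset_days = c(0L, 0L))
  out <- corrupt_record(pop[1, ], quiet, new_id = "dup1")
  expect_equal(out$record$record_id, "dup1")
  expect_length(out$manifest, 0)
  for (col in setdiff(names(pop), "record_id")) {
    expect_equal(out$record[[col]], pop[1, col][[1]], info = col)
  }
})

test_that("formatting-only corruption leaves cleaned fields intact", {
  pop <- generate_population(population_params(n_records = 300, seed = 80))
  inj <- inject_duplicates(pop, formatting_only_params(0.1), seed = 81)
  base <- inj$records[match(inj$truth$id_a, inj$records$record_id), ]
  dup <- inj$records[match(inj$truth$id_b, inj$records$record_id), ]
  # the truth pair columns are (base, dup) up to canonical id ordering
  swap <- !grepl("^C", base$record_id)
  tmp <- base[swap, ]; base[swap, ] <- dup[swap, ]; dup[swap, ] <- tmp
  expect_equal(clean_name(dup$first_name), clean_name(base$first_name))
  expect_equal(clean_name(dup$surname), clean_name(base$surname))
  expect_equal(normalize_ccc(dup$ccc_number)$canonical_text,
               normalize_ccc(base$ccc_number)$canonical_text)
  expect_equal(dup$date_of_birth, base$date_of_birth)
  expect_equal(build_match_key(dup)$key_string,
               build_match_key(base)$key_string)
})

test_that("beyond-tolerance birth shifts always break the age comparator", {
  pop <- generate_population(population_params(n_records = 100, seed = 82))
  far <- corruption_params(duplicate_rate = 0.2, p_typo_substitution = 0,
                           p_typo_transposition = 0, p_typo_deletion = 0,
                           p_typo_insertion = 0, p_reformat = 0,
                           p_middle_dropout = 0, p_ccc_reformat = 0,
                           p_dob_shift_within = 0, p_dob_shift_beyond = 1,
                           p_cross_scenario = 0)
  inj <- inject_duplicates(pop, far, seed = 83)
  base <- inj$records[match(inj$truth$id_a, inj$records$record_id), ]
  dup <- inj$records[match(inj$truth$id_b, inj$records$record_id), ]
  diffs <- compute_age_diff(base$date_of_birth, dup$date_of_birth,
                            base$year_of_birth, dup$year_of_birth)
  expect_true(all(diffs > 12))
  expect_true(all(grepl("dob_shift_beyond", inj$truth$manifest)))
})

test_that("typo positions favor indices beyond the fourth character", {
  set.seed(84)
  pos <- replicate(4000, cbsmatch:::sample_typo_pos(10))
  frac_late <- mean(pos > 4)
  # 6 late positions at weight 3 vs 4 early at weight 1: expect 18/22
  expect_equal(frac_late, 18 / 22, tolerance = 0.04)
})
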