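test_that("cluster resolution keeps the earliest diagnosis and merges gaps", {
  members <- make_cases(first = c("Grace", "Grace"), surname = "Anyiso",
                        middle = c(NA, "Akoth"), yob = 1994L,
                        dodx = as.Date(c("2015-02-01", "2015-04-01")),
                        ccc = c(NA, "12345-00009"))
  out <- resolve_cluster(members)
  expect_equal(out$record$record_id, "r001")
  expect_equal(out$record$date_of_diagnosis, as.Date("2015-02-01"))
  # append merge fills what the base lacks, from the duplicate
  expect_equal(out$record$middle_name, "Akoth")
  expect_equal(out$record$ccc_number, "12345-00009")
  expect_equal(nrow(out$conflicts), 0)
})

test_that("conflicting nonmissing values are logged, never overwritten", {
  members <- make_cases(first = c("Grace", "Grace"), surname = "Anyiso",
                        yob = 1994L,
                        dodx = as.Date(c("2015-02-01", "2015-04-01")),
                        ccc = c("11111-00001", "22222-00002"))
  out <- resolve_cluster(members)
  expect_equal(out$record$ccc_number, "11111-00001")
  expect_equal(out$conflicts$field, "ccc_number")
  expect_equal(out$conflicts$donor_value, "22222-00002")
})

test_that("equal diagnosis dates break ties by completeness then id", {
  members <- make_cases(first = c("Grace", "Grace"), surname = "Anyiso",
                        middle = c(NA, "Akoth"), yob = 1994L,
                        dodx = as.Date(c("2015-02-01", "2015-02-01")))
  out <- resolve_cluster(members)
  expect_equal(out$record$record_id, "r002")   # more complete record wins
  same <- make_cases(first = c("Grace", "Grace"), surname = "Anyiso",
                     yob = 1994L,
                     dodx = as.Date(c("2015-02-01", "2015-02-01")))
  expect_equal(resolve_cluster(same)$record$record_id, "r001")
})

test_that("dedup accounting identities hold on forced examples", {
  rec <- make_cases(first = c("Ann", "Beth", "Carol", "Dora", "Grace",
                              "Grace"),
                    surname = c("Okoth", "Ouma", "Otieno", "Owino",
                                "Anyiso", "Anyiso"),
                    yob = c(1960L, 1965L, 1970L, 1975L, 1994L, 1994L))
  res <- dedup(rec, match_config("jaro_winkler"))
  expect_equal(res$n_duplicates, 1)
  expect_equal(res$total_unique, 5)
  expect_equal(nrow(res$retained), 5)
  expect_equal(nrow(res$master_index), 6)
  expect_equal(sum(res$master_index$retained), 5)
  # no duplicates injected
  res0 <- dedup(rec[1:4, ], match_config("jaro_winkler"))
  expect_equal(res0$n_duplicates, 0)
  expect_equal(res0$total_unique, 4)
  # three mutually matching records collapse to one
  tri <- make_cases(first = "Grace", surname = "Anyiso", yob = 1994L,
                    id = c("x1", "x2", "x3"))
  res3 <- dedup(tri, match_config("jaro_winkler"))
  expect_equal(res3$n_duplicates, 2)
  expect_equal(res3$total_unique, 1)
})

test_that("dedup is idempotent on its own retained output", {
  pop <- generate_population(population_params(n_records = 600, seed = 61))
  inj <- inject_duplicates(pop, corruption_params(duplicate_rate = 0.06),
                           seed = 62)
  for (m in c("deterministic", "jaro_winkler")) {
    res <- dedup(inj$records, match_config(m))
    expect_equal(res$total_unique,
                 res$n_input - sum(lengths(res$clusters) - 1))
    again <- dedup(res$retained, match_config(m))
    expect_equal(again$n_duplicates, 0)
    expect_equal(again$total_unique, res$total_unique)
  }
})

test_that("conservation: cluster members plus singletons cover the input", {
  pop <- generate_population(population_params(n_records = 500, seed = 63))
  inj <- inject_duplicates(pop, corruption_params(), seed = 64)
  res <- dedup(inj$records, match_config("jaro_winkler"))
  in_cluster <- unlist(res$clusters)
  expect_equal(sum(lengths(res$clusters)) +
                 (res$n_input - length(in_cluster)), res$n_input)
  expect_false(anyDuplicated(in_cluster) > 0)
  expect_setequal(res$master_index$record_id, inj$records$record_id)
  # the retained record is at least as complete as the earliest member
  for (ids in res$clusters[1:min(5, length(res$clusters))]) {
    rows <- inj$records[inj$records$record_id %in% ids, ]
    earliest <- rows[order(rows$date_of_diagnosis,
                           -rowSums(!is.na(rows)), rows$record_id)[1], ]
    kept <- res$retained[res$retained$record_id == earliest$record_id, ]
    expect_equal(nrow(kept), 1)
    expect_gte(sum(!is.na(kept)), sum(!is.na(earliest)))
    expect_equal(kept$date_of_diagnosis, min(rows$date_of_diagnosis))
  }
})

test_that("yield report cells, All row, and Unique row line up", {
  rec <- make_cases(first = c(name_pool("first")[1:98], "Grace", "Grace"),
                    surname = c(name_pool("surname")[1:98], "Anyiso",
                                "Anyiso"),
                    yob = c(1900L + 1:98, 1994L, 1994L))
  res <- dedup(rec, match_config("jaro_winkler"))
  rep1 <- yield_report(list(jaro_winkler = res))
  expect_equal(rep1$counts["HTS", 1], res$n_duplicates)
  expect_equal(rep1$counts["All", 1],
               sum(rep1$counts[c("HTS"), 1]))
  expect_equal(rep1$counts["Unique", 1], 100 - rep1$counts["All", 1])
  # formatting contract: count (pct of scenario size, one decimal)
  expect_equal(rep1$formatted["HTS", 1],
               sprintf("%d (%.1f)", res$n_duplicates,
                       100 * res$n_duplicates / 100))
  # mismatched input sizes across results must error
  other <- dedup(rec[1:50, ], match_config("jaro"))
  expect_error(yield_report(list(a = res, b = other)), "sizes differ")
})

test_that("cross-method report sums scenarios into the All row", {
  pop <- generate_population(population_params(n_records = 400, seed = 65))
  inj <- inject_duplicates(pop, corruption_params(), seed = 66)
  results <- lapply(setNames(nm = c("deterministic", "jaro", "jaro_winkler")),
                    function(m) dedup(inj$records, match_config(m)))
  rep3 <- yield_report(results)
  scen <- setdiff(rownames(rep3$counts), c("All", "Unique"))
  for (m in colnames(rep3$counts)) {
    expect_equal(rep3$counts["All", m], sum(rep3$counts[scen, m]))
    expect_equal(rep3$counts["Unique", m],
                 rep3$n_input - rep3$counts["All", m])
  }
})
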