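write_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

minimal_header <- paste("record_id,source_scenario,first_name,middle_name,",
                        "surname,gender,date_of_birth,date_of_diagnosis",
                        sep = "")

test_that("read_cases preserves rows and standardizes fields", {
  path <- write_fixture(c(
    minimal_header,
    "a1,HTS,Grace,,Anyiso,F,1994-05-01,2015-02-01",
    "a2,hts-care,OTIENO,Akoth,Ouma,male,02/03/1983,15/01/2015",
    "a3,CARE,Mary,N/A,Okoth,f,1990-01-01,2015-06-30"))
  rec <- read_cases(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$record_id, c("a1", "a2", "a3"))
  expect_equal(rec$source_scenario, c("HTS", "HTS_CARE", "CARE"))
  expect_equal(rec$gender, c("female", "male", "female"))
  # day-first dialect
  expect_equal(rec$date_of_birth[2], as.Date("1983-03-02"))
  expect_equal(rec$date_of_diagnosis[2], as.Date("2015-01-15"))
  # sentinel missing tokens collapse to NA
  expect_true(is.na(rec$middle_name[1]) && is.na(rec$middle_name[3]))
  # year of birth derived from the date
  expect_equal(rec$year_of_birth, c(1994L, 1983L, 1990L))
})

test_that("missing mandatory column raises a schema error naming it", {
  path <- write_fixture(c("record_id,first_name,gender,date_of_birth,date_of_diagnosis",
                          "a1,Grace,F,1994-05-01,2015-02-01"))
  expect_error(read_cases(path), "surname")
})

test_that("empty file yields an empty collection, not an error", {
  path <- write_fixture(minimal_header)
  rec <- read_cases(path)
  expect_equal(nrow(rec), 0)
})

test_that("impossible calendar dates become absent with a warning", {
  path <- write_fixture(c(
    minimal_header,
    "a1,HTS,Grace,,Anyiso,F,1994-05-01,31/02/2015"))
  expect_warning(rec <- read_cases(path), "unparseable date")
  expect_true(is.na(rec$date_of_diagnosis[1]))
  expect_false(is.na(rec$date_of_birth[1]))
})

test_that("extra columns are carried through unmodified", {
  path <- write_fixture(c(
    paste0(minimal_header, ",art_start"),
    "a1,HTS,Grace,,Anyiso,F,1994-05-01,2015-02-01,2015-03-01"))
  rec <- read_cases(path)
  expect_equal(rec$art_start, "2015-03-01")
  expect_equal(attr(rec, "extra_fields"), "art_start")
})

test_that("write/read round trip reproduces standardized fields", {
  rec <- make_cases(first = c("Grace", "Otieno"), surname = c("Anyiso", "Ouma"),
                    middle = c(NA, "Akoth"), scenario = c("HTS", "CARE"),
                    ccc = c(NA, "12345-00001"))
  path <- tempfile(fileext = ".csv")
  write_cases(rec, path)
  back <- read_cases(path)
  for (col in names(rec)) {
    expect_equal(back[[col]], rec[[col]], info = col)
  }
})

test_that("exclusions partition the input with diagnosis-date precedence", {
  rec <- make_cases(first = letters[1:10], surname = letters[11:20])
  rec$date_of_diagnosis[c(2, 5)] <- NA
  rec$date_of_birth[7] <- NA
  rec$year_of_birth[7] <- NA
  # record 2 also misses its birth date: diagnosis-date rule fires first
  rec$date_of_birth[2] <- NA
  rec$year_of_birth[2] <- NA
  out <- apply_exclusions(rec)
  expect_equal(nrow(out$kept), 7)
  expect_equal(nrow(out$excluded), 3)
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(rec))
  reasons <- setNames(out$excluded$exclusion_reason, out$excluded$record_id)
  expect_equal(unname(reasons[c("r002", "r005")]),
               rep("missing_date_of_diagnosis", 2))
  expect_equal(unname(reasons["r007"]), "missing_date_of_birth")
  # identity case
  clean <- apply_exclusions(make_cases(first = "a", surname = "b"))
  expect_equal(nrow(clean$excluded), 0)
})

test_that("exclusion partition holds for random missingness patterns", {
  set.seed(41)
  for (i in 1:20) {
    rec <- make_cases(first = letters[1:15], surname = letters[1:15])
    rec$date_of_diagnosis[runif(15) < 0.3] <- NA
    drop_dob <- runif(15) < 0.3
    rec$date_of_birth[drop_dob] <- NA
    rec$year_of_birth[drop_dob] <- NA
    out <- apply_exclusions(rec)
    expect_equal(nrow(out$kept) + nrow(out$excluded), 15)
    expect_length(intersect(out$kept$record_id, out$excluded$record_id), 0)
  }
})

test_that("field profiling counts distinct standardized values", {
  rec <- make_cases(first = c("Robert", "RUPERT", "Grace", "grace"),
                    surname = c("Otieno", "Otieno", "Anyiso", "Anyiso"),
                    gender = c("male", "female", "female", "female"))
  prof <- profile_fields(rec)
  row <- function(f) prof[prof$field == f, ]
  expect_equal(row("gender")$distinct_count, 2)
  expect_equal(row("gender")$completeness, 100)
  # raw first names: 3 distinct cleaned; soundex merges robert/rupert
  expect_equal(row("first_name")$distinct_count, 3)
  expect_equal(row("soundex_first_name")$distinct_count, 2)
  # all middle names absent
  expect_equal(row("middle_name")$completeness, 0)
  expect_equal(row("middle_name")$denominator, 0)
  expect_error(profile_fields(rec, "no_such_field"), "no_such_field")
})

test_that("phonetic coarsening shows in profiles of generated data", {
  pop <- generate_population(population_params(n_records = 300, seed = 99))
  prof <- profile_fields(pop)
  g <- function(f) prof$distinct_count[prof$field == f]
  expect_lte(g("soundex_first_name"), g("first_name"))
  expect_lte(g("phonetic_middle_name"), g("middle_name"))
  expect_lte(g("phonetic_surname"), g("surname"))
})
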