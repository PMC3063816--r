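# Admission-record I/O, validation, and the packaged worked-example counts.

test_that("write/read round trip is the identity on valid records", {
  cfg <- flat_config(60, class_weights = c(0.5, 0.3, 0.2, 0, 0, 0, 0, 0))
  rec <- generate_cohort(cfg, seed = 3)
  expect_gt(nrow(rec), 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_admissions(rec, path)
  back <- read_admissions(path)
  expect_identical(nrow(back), nrow(rec))
  for (col in admission_columns) {
    a <- rec[[col]]; b <- back[[col]]
    if (is.factor(a)) { a <- as.character(a); b <- as.character(b) }
    expect_equal(b, a, info = col)
  }
  # byte-stable on a second write
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_admissions(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("day cases (los 0 on a same-day stay) survive the round trip", {
  rec <- make_record("r1", "p1", "2004-05-01", "2004-05-01", los = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_admissions(rec, path)
  back <- read_admissions(path)
  expect_identical(back$los_days, 0L)
  expect_identical(back$admission_date, back$discharge_date)
})

test_that("an empty file with a header yields an empty collection and back", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_admissions(make_record("x", "p", "2004-01-01",
                               "2004-01-02")[0, ], path)
  out <- read_admissions(path)
  expect_identical(nrow(out), 0L)
  expect_true(all(admission_columns %in% names(out)))
  # two clean rows, two distinct patients
  two <- make_records(
    make_record("r1", "p1", "2004-01-01", "2004-01-03"),
    make_record("r2", "p2", "2004-02-01", "2004-02-02"))
  write_admissions(two, path)
  back <- read_admissions(path)
  expect_identical(nrow(back), 2L)
  expect_identical(length(unique(back$patient_id)), 2L)
})

test_that("strict validation aborts naming the offending record", {
  bad <- make_records(
    make_record("ok-1", "p1", "2004-01-01", "2004-01-05"),
    make_record("bad-1", "p2", "2004-03-10", "2004-03-01"))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- bad
  out$admission_date <- format(out$admission_date)
  out$discharge_date <- format(out$discharge_date)
  out$sex <- as.character(out$sex); out$emergency <- as.integer(out$emergency)
  out$charlson_band <- as.character(out$charlson_band)
  out$ccs_group <- as.character(out$ccs_group)
  out$died <- as.integer(out$died)
  utils::write.csv(out, path, row.names = FALSE)
  expect_error(read_admissions(path, strict = TRUE), "bad-1")
  lenient <- suppressMessages(read_admissions(path, strict = FALSE))
  expect_identical(nrow(lenient), 1L)
  expect_identical(attr(lenient, "dropped")$record_id, "bad-1")
})

test_that("structural problems in the file abort", {
  path <- withr::local_tempfile(fileext = ".csv")
  expect_error(read_admissions(file.path(tempdir(), "nope.csv")),
               "not found")
  writeLines("record_id,patient_id", path)
  expect_error(read_admissions(path), "missing column")
  dup <- make_records(
    make_record("r1", "p1", "2004-01-01", "2004-01-02"),
    make_record("r1", "p2", "2004-01-05", "2004-01-06"))
  write_admissions(dup, path)
  expect_error(read_admissions(path), "duplicate")
})

test_that("los/date invariants are enforced", {
  r <- make_record("r1", "p1", "2004-01-01", "2004-01-03", los = 5)
  expect_error(validate_admissions(r), "los_days")
  r2 <- make_record("r2", "p1", "2004-01-01", "2004-01-03", los = 0)
  expect_error(validate_admissions(r2), "los_days")
})

test_that("worked-example counts match the printed per-class tables", {
  pt <- worked_example_counts("patient")
  at <- worked_example_counts("admission")
  tot <- pt[pt$class == "Total", ]
  expect_identical(tot$n_patients, 240662L)
  expect_identical(tot$n_admissions, 418566L)
  expect_identical(tot$observed_deaths, 15227L)
  expect_equal(tot$predicted_deaths, 16379)

  m1 <- pt[pt$class == "1", ]
  expect_identical(m1$n_patients, 164884L)
  expect_identical(m1$observed_deaths, 8836L)
  expect_equal(m1$predicted_deaths, 6971)

  a20 <- at[at$class == ">20", ]
  expect_identical(a20$n_admissions, 5437L)
  expect_identical(a20$observed_deaths, 55L)
  expect_equal(a20$predicted_deaths, 57)

  body_p <- pt[pt$class != "Total", ]
  body_a <- at[at$class != "Total", ]
  expect_identical(sum(body_p$observed_deaths), 15227L)
  # a death at the n-th admission implies total frequency m = n, so the
  # observed-death columns of the two views are identical class by class
  expect_identical(body_p$observed_deaths, body_a$observed_deaths)
  expect_identical(body_p$observed_deaths,
                   c(8836L, 2868L, 1377L, 727L, 695L, 404L, 265L, 55L))
  # single-m classes: admissions = m x patients
  m <- 1:4
  expect_identical(body_p$n_admissions[m], m * body_p$n_patients[m])
  expect_error(worked_example_counts("bogus"))
})
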