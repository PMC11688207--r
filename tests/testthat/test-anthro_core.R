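test_that("a well-formed cohort file parses with no rejects and round-trips", {
  path <- write_fixture_cohort(withr::local_tempfile(fileext = ".csv"))
  cohort <- read_cohort(path)
  expect_equal(nrow(cohort$records), 3)
  expect_equal(nrow(cohort$rejects), 0)

  out <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, out)
  again <- read_cohort(out)
  expect_equal(again$records, cohort$records, tolerance = 1e-12)
})

test_that("invalid rows are rejected with reasons, never silently dropped", {
  path <- write_fixture_cohort(
    withr::local_tempfile(fileext = ".csv"),
    tweak = function(d) {
      d$height_cm_rep1 <- as.character(d$height_cm_rep1)
      d$height_cm_rep1[2] <- "abc"
      d$muac_cm_rep2[3] <- 45.0
      d
    })
  cohort <- read_cohort(path)
  expect_equal(nrow(cohort$records), 1)
  expect_setequal(cohort$rejects$id, c("a2", "a3"))
  expect_true(any(grepl("non-numeric height",
                        cohort$rejects$reason[cohort$rejects$id == "a2"])))
  expect_true(any(cohort$rejects$reason[cohort$rejects$id == "a3"] ==
                    "out of plausibility window"))
})

test_that("ages outside the study window and missing pairs are rejected", {
  path <- write_fixture_cohort(
    withr::local_tempfile(fileext = ".csv"),
    tweak = function(d) {
      d$age_months[1] <- 200L
      d$muac_cm_rep1[2] <- NA
      d$muac_cm_rep2[2] <- NA
      d
    })
  cohort <- read_cohort(path)
  expect_equal(cohort$records$id, "a3")
  expect_true("outside study age window" %in%
                cohort$rejects$reason[cohort$rejects$id == "a1"])
  expect_true("measurement missing" %in%
                cohort$rejects$reason[cohort$rejects$id == "a2"])
})

test_that("a missing mapped column is a schema error", {
  path <- write_fixture_cohort(
    withr::local_tempfile(fileext = ".csv"),
    tweak = function(d) { d$muac_cm_rep2 <- NULL; d })
  expect_error(read_cohort(path), class = "schema_error")
})

test_that("replicate averaging is the mean, falls back to the present value", {
  expect_equal(average_replicates(20.0, 20.2), 20.1)
  expect_equal(average_replicates(19.1, 19.1), 19.1)
  expect_equal(average_replicates(20.0, NA), 20.0)
  expect_error(average_replicates(NA_real_, NA_real_),
               class = "missing_measurement_error")
})

test_that("averaging is symmetric and bounded by its inputs", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, 10, 40); b <- runif(1, 10, 40)
    m <- average_replicates(a, b)
    expect_equal(m, average_replicates(b, a))
    expect_gte(m, min(a, b))
    expect_lte(m, max(a, b))
  }
})

test_that("completed months match the printed examples", {
  expect_equal(exact_age_months(as.Date("2010-03-15"), as.Date("2021-03-15")),
               132L)
  expect_equal(exact_age_months(as.Date("2010-03-16"), as.Date("2021-03-15")),
               131L)
  expect_equal(exact_age_months(as.Date("2011-01-31"), as.Date("2021-02-28")),
               120L)
  expect_error(exact_age_months(as.Date("2021-03-15"), as.Date("2021-03-15")),
               class = "chronology_error")
})

test_that("completed months agree with a brute-force calendar oracle", {
  set.seed(7)
  dobs <- as.Date("2008-01-01") + sample(0:2000, 40)
  for (dob in as.list(dobs)) {
    interview <- dob + sample(200:4500, 1)
    expect_equal(exact_age_months(dob, interview),
                 oracle_age_months(dob, interview),
                 info = paste(dob, interview))
  }
  # exact-anniversary property: dob + k whole months gives exactly k
  d0 <- as.Date("2010-05-15")
  for (k in c(1, 11, 12, 60, 131)) {
    lt <- as.POSIXlt(d0)
    lt$mon <- lt$mon + k
    expect_equal(exact_age_months(d0, as.Date(lt)), as.integer(k))
  }
})

test_that("frequency tables use the declared denominator and round half up", {
  expect_equal(percent_of(884, 913, 1), 96.8)
  expect_equal(percent_of(543, 884, 2), 61.43)
  expect_equal(percent_of(0, 50, 2), 0)
  ft <- frequency_table(c(rep("x", 543), rep("y", 341)))
  expect_equal(sum(ft$count), 884)
  expect_equal(ft$percent[ft$level == "x"], 61.43)
  expect_equal(sum(ft$percent), 100, tolerance = 0.02)
  expect_error(frequency_table(character(), denominator = 0),
               class = "degenerate_input_error")
})
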