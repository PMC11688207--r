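test_that("bmi is weight over squared height in metres", {
  expect_equal(bmi(45, 150), 20)
  expect_equal(bmi(38.5, 150), 17.1111, tolerance = 1e-4)
  expect_equal(bmi(20, 200), 5)
  expect_error(bmi(-1, 150), class = "domain_error")
})

test_that("LMS z-score matches its closed forms", {
  expect_equal(lms_z(16, -1.4, 16, 0.11), 0)           # median maps to 0
  expect_equal(lms_z(17.6, 1, 16, 0.1), 1)             # linear case
  expect_equal(lms_z(13, -0.5, 16, 0.11), -1.989, tolerance = 5e-4)
  expect_equal(lms_z(17, 0, 16, 0.11), log(17 / 16) / 0.11)  # L = 0 limit
  expect_error(lms_z(0, 1, 16, 0.1), class = "domain_error")
})

test_that("lms_z is strictly increasing in the measurement", {
  for (L in c(-2, -1.4, -0.5, 0, 1)) {
    x <- seq(10, 30, by = 0.5)
    z <- lms_z(x, L, 16.5, 0.11)
    expect_true(all(diff(z) > 0), info = paste("L =", L))
  }
})

test_that("inverse_lms round-trips with lms_z to 1e-9", {
  for (L in c(-2, -1.4, -0.5, 0, 1)) {
    z <- seq(-4, 4, by = 0.25)
    x <- inverse_lms(z, L, 16.5, 0.11)
    expect_equal(lms_z(x, L, 16.5, 0.11), z, tolerance = 1e-9,
                 info = paste("L =", L))
  }
  expect_equal(inverse_lms(0, -1.4, 16.5, 0.11), 16.5)
  expect_equal(inverse_lms(2, 1, 16, 0.1), 19.2)
  expect_error(inverse_lms(-11, 1, 16, 0.1), class = "domain_error")
})

test_that("the restricted adjustment touches only |z| > 3", {
  r <- restricted_z(inverse_lms(2.5, -1.4, 16, 0.11), -1.4, 16, 0.11)
  expect_equal(r$z, 2.5, tolerance = 1e-9)
  expect_false(r$adjusted)
  r3 <- restricted_z(inverse_lms(3, -1.4, 16, 0.11), -1.4, 16, 0.11)
  expect_equal(r3$z, 3, tolerance = 1e-9)
  expect_false(r3$adjusted)
  # with L = 1 the adjustment is exactly linear so restricted = raw
  r45 <- restricted_z(23.2, 1, 16, 0.1)
  expect_equal(r45$z, 3 + (23.2 - 20.8) / (20.8 - 19.2))
  expect_equal(r45$z, 4.5)
  expect_true(r45$adjusted)
  rn <- restricted_z(8.8, 1, 16, 0.1)  # raw z = -4.5
  expect_equal(rn$z, -3 + (8.8 - 11.2) / (12.8 - 11.2))
  expect_equal(rn$z, -4.5)
  expect_true(rn$adjusted)
})

test_that("classification boundaries follow the WHO 2007 inequalities", {
  expect_equal(as.character(classify_baz(-3.2)), "severe_thinness")
  expect_equal(as.character(classify_baz(-2.5)), "thinness")
  expect_equal(as.character(classify_baz(c(-3, -2, 0, 1))),
               c("thinness", "normal", "normal", "normal"))
  expect_equal(as.character(classify_baz(c(1.5, 2, 2.5))),
               c("overweight", "overweight", "obesity"))
  expect_error(classify_baz(NaN), class = "domain_error")
})

test_that("baz composes bmi, restricted z and classification", {
  tab <- synthetic_lms()
  m132 <- tab$M[tab$month == 132]
  rec <- data.frame(id = "x", age_months = 132L, age_years = 11L,
                    height_cm = 150, weight_kg = m132 * 1.5^2,
                    muac_cm = 20)
  out <- baz(rec, tab)
  expect_equal(out$z, 0, tolerance = 1e-12)
  expect_equal(as.character(out$category), "normal")

  # constructed thinness case via the inverse transform at month 150
  r150 <- tab[tab$month == 150, ]
  b <- inverse_lms(-2.3, r150$L, r150$M, r150$S)
  rec2 <- data.frame(id = "y", age_months = 150L, age_years = 12L,
                     height_cm = 150, weight_kg = b * 1.5^2, muac_cm = 18)
  out2 <- baz(rec2, tab)
  expect_equal(out2$z, -2.3, tolerance = 1e-9)
  expect_equal(as.character(out2$category), "thinness")

  # coverage boundary: 179 works, 180 is out of range
  rec$age_months <- 179L
  expect_silent(baz(rec, tab))
  rec$age_months <- 180L
  expect_error(baz(rec, tab), class = "reference_range_error")
})

test_that("LMS tables are validated for layout and contiguity", {
  tab <- synthetic_lms()
  expect_s3_class(tab, "lms_table")
  gap <- as.data.frame(tab)[-5, ]
  expect_error(lms_table(gap), class = "schema_error")
  bad <- as.data.frame(tab); bad$M[1] <- -1
  expect_error(lms_table(bad), class = "domain_error")

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  expect_equal(read_lms(path)$M, tab$M)
  expect_error(read_lms("no-such-file.csv"), class = "file_error")
})
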