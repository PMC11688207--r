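# in-code fixtures shared across the suite

# a tiny well-formed cohort CSV; `tweak` can overwrite cells to inject
# validation failures
write_fixture_cohort <- function(path, tweak = NULL) {
  d <- data.frame(
    id = c("a1", "a2", "a3"),
    sex = "female",
    age_months = c(132L, 150L, 179L),
    school_type = c("governmental", "nongovernmental", "governmental"),
    height_cm_rep1 = c(140.0, 151.2, 158.4),
    height_cm_rep2 = c(140.4, 151.0, 158.0),
    weight_kg_rep1 = c(32.1, 40.3, 48.6),
    weight_kg_rep2 = c(32.3, 40.1, 48.8),
    muac_cm_rep1 = c(18.2, 20.5, 23.1),
    muac_cm_rep2 = c(18.4, 20.3, 23.3),
    stringsAsFactors = FALSE
  )
  if (!is.null(tweak)) d <- tweak(d)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

# flat-coefficient reference over the study window; linear special case
# (L = 1) makes several closed forms exact
linear_lms <- function(L = 1, M = 16, S = 0.1, months = 120:179) {
  lms_table(data.frame(sex = "female", month = months, L = L, M = M, S = S))
}

# exhaustive pairwise Mann-Whitney AUC with ties counted one half,
# positive-if-low orientation (independent of roc_curve's sweep)
mw_auc <- function(values, condition) {
  x <- values[condition]; y <- values[!condition]
  mean(outer(x, y, function(a, b) (a < b) + 0.5 * (a == b)))
}

# calendar oracle for completed months: the k-th month anniversary
# falls on the dob's day-of-month when that day exists in the target
# month, otherwise on the first day of the following month
oracle_age_months <- function(dob, interview) {
  dob <- as.POSIXlt(dob)
  days_in <- function(y, m) {
    leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
    c(31, 28 + leap, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
  }
  k <- 0L
  repeat {
    mon <- dob$mon + k + 1L
    y <- dob$year + 1900L + mon %/% 12L
    m <- mon %% 12L + 1L
    ann <- if (dob$mday <= days_in(y, m)) {
      as.Date(sprintf("%04d-%02d-%02d", y, m, dob$mday))
    } else {
      as.Date(sprintf("%04d-%02d-01", y + (m == 12L), m %% 12L + 1L))
    }
    if (ann > as.Date(interview)) return(k)
    k <- k + 1L
  }
}
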