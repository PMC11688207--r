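#' Body mass index
#' @param weight_kg,height_cm positive numerics.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(45, 150) # 20
bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop_muac("weight and height must be positive", "domain_error")
  }
  weight_kg / (height_cm / 100)^2
}

#' Read an LMS growth-reference table
#'
#' Expects the layout of the published WHO reference files: columns
#' `sex`, `month`, `L`, `M`, `S` (column names case-insensitive;
#' `age_months` accepted for `month`). Coverage must be contiguous in
#' months within each sex.
#'
#' @param path CSV path.
#' @return `lms_table` data frame.
#' @export
read_lms <- function(path) {
  if (!file.exists(path)) {
    stop_muac(sprintf("LMS file not found: %s", path), "file_error")
  }
  d <- utils::read.csv(path, check.names = FALSE)
  names(d) <- tolower(names(d))
  if ("age_months" %in% names(d) && !"month" %in% names(d)) {
    names(d)[names(d) == "age_months"] <- "month"
  }
  lms_table(d)
}

#' Validate an LMS table
#' @param d data frame with sex, month, L, M, S (names case-insensitive).
#' @return `lms_table` data frame ordered by sex, month.
#' @export
lms_table <- function(d) {
  names(d) <- sub("^l$", "L", sub("^m$", "M", sub("^s$", "S", names(d))))
  need <- c("sex", "month", "L", "M", "S")
  if (!all(need %in% names(d))) {
    stop_muac(sprintf("LMS table must have columns %s",
                      paste(need, collapse = ", ")), "schema_error")
  }
  if (any(d$M <= 0) || any(d$S <= 0)) {
    stop_muac("LMS table requires M > 0 and S > 0", "domain_error")
  }
  d <- d[order(d$sex, d$month), need]
  for (s in unique(d$sex)) {
    m <- d$month[d$sex == s]
    if (anyDuplicated(m) || !all(diff(m) == 1)) {
      stop_muac("LMS coverage must be contiguous monthly without duplicates",
                "schema_error")
    }
  }
  class(d) <- c("lms_table", "data.frame")
  d
}

#' Look up the LMS row for a completed month
#'
#' Exact completed-month lookup with no interpolation, mirroring the
#' WHO reference software's month indexing.
#'
#' @param table `lms_table`.
#' @param age_months integer vector of completed months.
#' @param sex sex level present in the table.
#' @return data frame of L, M, S rows aligned with `age_months`.
#' @export
lms_lookup <- function(table, age_months, sex = "female") {
  sub <- table[table$sex == sex, ]
  idx <- match(age_months, sub$month)
  if (any(is.na(idx))) {
    bad <- age_months[is.na(idx)][1]
    stop_muac(sprintf(
      "age %d months outside reference coverage (%d-%d)", bad,
      min(sub$month), max(sub$month)), "reference_range_error")
  }
  sub[idx, c("L", "M", "S"), drop = FALSE]
}

#' LMS z-score
#'
#' z = ((x/M)^L - 1) / (L*S), with the continuity limit
#' z = log(x/M)/S when L = 0.
#'
#' @param x positive measured value (same units as M).
#' @param L,M,S reference coefficients (vectors recycled against x).
#' @return z-score in SD units.
#' @export
lms_z <- function(x, L, M, S) {
  if (any(x <= 0)) stop_muac("measured value must be positive", "domain_error")
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z0 <- L == 0
  out <- ((x / M)^L - 1) / (L * S)
  out[z0] <- log(x[z0] / M[z0]) / S[z0]
  out
}

#' Invert the LMS transform
#'
#' x = M * (1 + L*S*z)^(1/L) (L = 0: x = M * exp(S*z)). Round-trips with
#' [lms_z()] to numerical precision.
#'
#' @param z z-score.
#' @param L,M,S reference coefficients.
#' @return measured value on the original scale.
#' @export
inverse_lms <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  arg <- 1 + L * S * z
  if (any(L != 0 & arg <= 0)) {
    stop_muac("z outside the domain of the LMS inverse (1 + L*S*z <= 0)",
              "domain_error")
  }
  z0 <- L == 0
  out <- M * arg^(1 / L)
  out[z0] <- M[z0] * exp(S[z0] * z[z0])
  out
}

#' Restricted z-score (WHO AnthroPlus convention)
#'
#' Raw z-scores beyond +/-3 SD are rescaled linearly in the measurement:
#' above +3, z* = 3 + (x - SD3pos)/(SD3pos - SD2pos) where SDk is the
#' measurement at z = k; symmetric below -3. This caps the influence of
#' extreme (often erroneous) measurements while keeping the +/-3
#' boundary and the category fixed.
#'
#' @inheritParams lms_z
#' @return list with `z` (restricted z-score) and `adjusted` (logical,
#'   TRUE where the restriction changed the raw value's scale).
#' @export
restricted_z <- function(x, L, M, S) {
  raw <- lms_z(x, L, M, S)
  z <- raw
  hi <- raw > 3
  lo <- raw < -3
  if (any(hi)) {
    sd3 <- inverse_lms(3, L, M, S)
    sd2 <- inverse_lms(2, L, M, S)
    z[hi] <- (3 + (x - sd3) / (sd3 - sd2))[hi]
  }
  if (any(lo)) {
    sd3n <- inverse_lms(-3, L, M, S)
    sd2n <- inverse_lms(-2, L, M, S)
    z[lo] <- (-3 + (x - sd3n) / (sd2n - sd3n))[lo]
  }
  list(z = z, adjusted = hi | lo)
}

#' WHO 2007 BMI-for-age categories
#'
#' z < -3 severe thinness; -3 <= z < -2 thinness; -2 <= z <= +1 normal;
#' +1 < z <= +2 overweight; z > +2 obesity.
#'
#' @param z finite BMI-for-age z-score(s).
#' @return factor with levels severe_thinness, thinness, normal,
#'   overweight, obesity.
#' @export
classify_baz <- function(z) {
  if (any(!is.finite(z))) stop_muac("z must be finite", "domain_error")
  lev <- c("severe_thinness", "thinness", "normal", "overweight", "obesity")
  out <- cut(z, breaks = c(-Inf, -3, -2, 1, 2, Inf), labels = lev,
             right = FALSE)
  # cut() with right = FALSE puts boundaries in the upper class; the
  # convention here needs -3 -> thinness, -2 -> normal (correct with
  # right = FALSE) but +1 -> normal and +2 -> overweight (upper-closed):
  out[z == 1] <- "normal"
  out[z == 2] <- "overweight"
  factor(as.character(out), levels = lev)
}

#' BMI-for-age z-scores and categories for an averaged cohort
#'
#' Composes [bmi()], [restricted_z()] at the completed-month reference
#' row and [classify_baz()].
#'
#' @param averaged data frame from [average_cohort()].
#' @param table `lms_table` covering all ages present.
#' @param sex sex level to look up.
#' @param restricted apply the restricted-z adjustment (default TRUE).
#' @return `averaged` with bmi, z, category and adjusted columns.
#' @export
baz <- function(averaged, table, sex = "female", restricted = TRUE) {
  row <- lms_lookup(table, averaged$age_months, sex)
  b <- bmi(averaged$weight_kg, averaged$height_cm)
  if (restricted) {
    rz <- restricted_z(b, row$L, row$M, row$S)
  } else {
    rz <- list(z = lms_z(b, row$L, row$M, row$S),
               adjusted = rep(FALSE, length(b)))
  }
  averaged$bmi <- b
  averaged$z <- rz$z
  averaged$category <- classify_baz(rz$z)
  averaged$adjusted <- rz$adjusted
  averaged
}

#' Synthetic LMS reference fixture
#'
#' A smooth, plausible BMI-for-age reference for girls aged 120-179
#' months: L = -1.4, S = 0.11, M = 16 + 0.04 * (month - 120) kg/m^2.
#' These are explicitly NOT the WHO 2007 values; the real WHO table is
#' a drop-in replacement via [read_lms()].
#'
#' @param months integer months covered.
#' @param sex sex label.
#' @return `lms_table`.
#' @export
synthetic_lms <- function(months = 120:179, sex = "female") {
  lms_table(data.frame(
    sex = sex, month = as.integer(months),
    L = -1.4, M = 16 + 0.04 * (months - 120), S = 0.11
  ))
}
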