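#' Default column mapping for cohort files
#'
#' Maps the internal field names onto the column names of a cohort CSV.
#' Any entry may be overridden, e.g. to read files whose MUAC replicates
#' are called `muac1`/`muac2`. `dob` and `interview_date` are optional;
#' when `age_months` is absent both must be present so the age in
#' completed months can be computed.
#'
#' @param ... name = "column" overrides of the defaults.
#' @return named character vector mapping field -> column name.
#' @export
cohort_schema <- function(...) {
  schema <- c(
    id = "id", sex = "sex", dob = "dob", interview_date = "interview_date",
    age_months = "age_months", school_type = "school_type",
    height_cm_rep1 = "height_cm_rep1", height_cm_rep2 = "height_cm_rep2",
    weight_kg_rep1 = "weight_kg_rep1", weight_kg_rep2 = "weight_kg_rep2",
    muac_cm_rep1 = "muac_cm_rep1", muac_cm_rep2 = "muac_cm_rep2"
  )
  over <- c(...)
  if (length(over)) schema[names(over)] <- over
  schema
}

#' Plausibility windows for anthropometric measurements
#'
#' Defaults: height 100-200 cm, weight 15-120 kg, MUAC 10-40 cm, age
#' 120-179 completed months (the 10-14 year study window). Values
#' outside a window are treated as recording errors and rejected, not
#' winsorised.
#'
#' @param height_cm,weight_kg,muac_cm,age_months length-2 numeric
#'   `c(min, max)` windows (inclusive).
#' @return named list of windows.
#' @export
plausibility_windows <- function(height_cm = c(100, 200),
                                 weight_kg = c(15, 120),
                                 muac_cm = c(10, 40),
                                 age_months = c(120, 179)) {
  list(height_cm = height_cm, weight_kg = weight_kg,
       muac_cm = muac_cm, age_months = age_months)
}

#' Read and validate a cohort file
#'
#' Reads a CSV of one row per participant with duplicate anthropometric
#' measurements, validates each row against the plausibility windows and
#' returns the clean records together with a reject report. Rows that
#' fail validation are collected with per-field reasons, never silently
#' dropped, so exclusion accounting (response rates) stays explicit.
#'
#' @param path cohort CSV path.
#' @param schema column mapping from [cohort_schema()], or a path to a
#'   YAML/JSON file holding such a mapping.
#' @param windows plausibility windows from [plausibility_windows()].
#' @return object of class `cohort`: a list with `records` (data frame of
#'   valid rows, replicate measurements numeric, `age_months` integer)
#'   and `rejects` (data frame id/field/reason).
#' @export
read_cohort <- function(path, schema = cohort_schema(),
                        windows = plausibility_windows()) {
  if (!file.exists(path)) {
    stop_muac(sprintf("cohort file not found: %s", path), "file_error")
  }
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- read_mapping_file(schema)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  required <- c("id", "sex")
  has_age <- schema[["age_months"]] %in% names(raw)
  has_dates <- all(schema[c("dob", "interview_date")] %in% names(raw))
  if (!has_age && !has_dates) {
    stop_muac("cohort file must provide age_months or dob + interview_date",
              "schema_error")
  }
  meas <- c("height_cm_rep1", "height_cm_rep2", "weight_kg_rep1",
            "weight_kg_rep2", "muac_cm_rep1", "muac_cm_rep2")
  missing_cols <- setdiff(schema[c(required, meas)], names(raw))
  if (length(missing_cols)) {
    stop_muac(sprintf("missing column(s): %s",
                      paste(missing_cols, collapse = ", ")), "schema_error")
  }

  n <- nrow(raw)
  ids <- raw[[schema[["id"]]]]
  rejects <- list()
  note <- function(i, field, reason) {
    rejects[[length(rejects) + 1]] <<- data.frame(
      id = ids[i], field = field, reason = reason,
      stringsAsFactors = FALSE)
  }

  num <- function(field) {
    col <- raw[[schema[[field]]]]
    col[col == ""] <- NA
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(out))
    for (i in bad) note(i, field, paste0("non-numeric ", sub("_(cm|kg)_rep[12]$", "", field)))
    out
  }
  vals <- lapply(stats::setNames(meas, meas), num)

  if (has_age) {
    age <- suppressWarnings(as.numeric(raw[[schema[["age_months"]]]]))
    bad <- which(is.na(age) & raw[[schema[["age_months"]]]] != "")
    for (i in bad) note(i, "age_months", "non-numeric age")
  } else {
    dob <- as.Date(raw[[schema[["dob"]]]])
    idate <- as.Date(raw[[schema[["interview_date"]]]])
    age <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (is.na(dob[i]) || is.na(idate[i])) {
        note(i, "dob", "unparseable date")
      } else if (dob[i] >= idate[i]) {
        note(i, "dob", "date of birth not before interview date")
      } else {
        age[i] <- exact_age_months(dob[i], idate[i])
      }
    }
  }

  window_of <- function(field) {
    windows[[sub("_rep[12]$", "", field)]]
  }
  ok <- rep(TRUE, n)
  for (field in meas) {
    w <- window_of(field)
    v <- vals[[field]]
    out_w <- which(!is.na(v) & (v < w[1] | v > w[2]))
    for (i in out_w) note(i, field, "out of plausibility window")
    # a pair with both replicates missing cannot be averaged downstream
  }
  both_na <- function(a, b) is.na(vals[[a]]) & is.na(vals[[b]])
  for (pair in list(c("height_cm_rep1", "height_cm_rep2"),
                    c("weight_kg_rep1", "weight_kg_rep2"),
                    c("muac_cm_rep1", "muac_cm_rep2"))) {
    miss <- which(both_na(pair[1], pair[2]))
    for (i in miss) note(i, sub("_rep1$", "", pair[1]), "measurement missing")
  }
  aw <- windows$age_months
  bad_age <- which(is.na(age) | age < aw[1] | age > aw[2] | age != floor(age))
  for (i in setdiff(bad_age, which(is.na(age)))) {
    note(i, "age_months", "outside study age window")
  }

  rej <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(id = character(), field = character(), reason = character(),
               stringsAsFactors = FALSE)
  ok <- !(ids %in% rej$id)

  records <- data.frame(
    id = ids[ok],
    sex = raw[[schema[["sex"]]]][ok],
    age_months = as.integer(age[ok]),
    school_type = if (schema[["school_type"]] %in% names(raw))
      raw[[schema[["school_type"]]]][ok] else NA_character_,
    stringsAsFactors = FALSE
  )
  for (field in meas) records[[field]] <- vals[[field]][ok]
  structure(list(records = records, rejects = rej), class = "cohort")
}

read_mapping_file <- function(path) {
  m <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_schema, as.list(unlist(m)))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d valid records, %d rejected rows\n",
              nrow(x$records), length(unique(x$rejects$id))))
  invisible(x)
}

#' Write a cohort and its reject report
#'
#' @param cohort `cohort` object or plain records data frame.
#' @param path output CSV for the records.
#' @param rejects_path optional CSV path for the reject report
#'   (id, field, reason).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, rejects_path = NULL) {
  records <- if (inherits(cohort, "cohort")) cohort$records else cohort
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(rejects_path) && inherits(cohort, "cohort")) {
    utils::write.csv(cohort$rejects, rejects_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Average duplicate measurements
#'
#' Each measurement is taken twice and the pair mean is used for
#' analysis. If exactly one replicate is present the present value is
#' used; both missing is an error.
#'
#' @param rep1,rep2 numeric vectors of replicate measurements (NA =
#'   missing).
#' @return vector of pair means.
#' @export
#' @examples
#' average_replicates(20.0, 20.2) # 20.1
average_replicates <- function(rep1, rep2) {
  if (length(rep1) != length(rep2)) {
    stop_muac("replicate vectors must have equal length", "domain_error")
  }
  if (any(is.na(rep1) & is.na(rep2))) {
    stop_muac("both replicates missing", "missing_measurement_error")
  }
  rowMeans(cbind(rep1, rep2), na.rm = TRUE)
}

#' Age in completed months between two dates
#'
#' The exact age is the difference between the interview date and the
#' date of birth, floored to whole calendar months: month `k` is
#' completed only once the k-th month anniversary day has been reached
#' (a day-of-month that does not exist in the target month, e.g. the
#' 31st in February, counts as not yet reached).
#'
#' @param dob,interview_date `Date` vectors.
#' @return integer completed months.
#' @export
#' @examples
#' exact_age_months(as.Date("2010-03-15"), as.Date("2021-03-15")) # 132
exact_age_months <- function(dob, interview_date) {
  dob <- as.Date(dob); interview_date <- as.Date(interview_date)
  if (any(dob >= interview_date)) {
    stop_muac("date of birth must precede the interview date",
              "chronology_error")
  }
  d1 <- as.POSIXlt(dob); d2 <- as.POSIXlt(interview_date)
  months <- 12L * (d2$year - d1$year) + (d2$mon - d1$mon) -
    as.integer(d2$mday < d1$mday)
  as.integer(months)
}

#' Completed years from completed months
#' @param age_months integer months.
#' @return integer `floor(age_months / 12)`.
#' @export
age_years <- function(age_months) as.integer(floor(age_months / 12))

#' Collapse duplicate measurements to one row per participant
#'
#' @param cohort `cohort` object or records data frame with `_rep1`/`_rep2`
#'   measurement columns.
#' @return data frame with id, age_months, age_years and the averaged
#'   height_cm, weight_kg, muac_cm.
#' @export
average_cohort <- function(cohort) {
  r <- if (inherits(cohort, "cohort")) cohort$records else cohort
  data.frame(
    id = r$id,
    age_months = r$age_months,
    age_years = age_years(r$age_months),
    height_cm = average_replicates(r$height_cm_rep1, r$height_cm_rep2),
    weight_kg = average_replicates(r$weight_kg_rep1, r$weight_kg_rep2),
    muac_cm = average_replicates(r$muac_cm_rep1, r$muac_cm_rep2),
    stringsAsFactors = FALSE
  )
}

#' Count/percentage table for a categorical variable
#'
#' @param x vector of levels (NA kept as its own level `"missing"`).
#' @param denominator denominator for the percentages; defaults to
#'   `length(x)` but can be larger, e.g. the sampled rather than the
#'   responding total.
#' @param digits decimals for the percent column (round half up).
#' @param variable label for the table.
#' @return `frequency_table` data frame with level, count, percent.
#' @export
frequency_table <- function(x, denominator = length(x), digits = 2,
                            variable = deparse(substitute(x))[1]) {
  if (denominator == 0) {
    stop_muac("denominator must be positive", "degenerate_input_error")
  }
  x <- as.character(x)
  x[is.na(x)] <- "missing"
  counts <- table(x)
  out <- data.frame(
    variable = variable,
    level = names(counts),
    count = as.integer(counts),
    percent = percent_of(as.integer(counts), denominator, digits),
    stringsAsFactors = FALSE
  )
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Percentage of a count over a denominator
#'
#' @param count,denominator counts.
#' @param digits decimals (round half up).
#' @return `100 * count / denominator`, rounded.
#' @export
#' @examples
#' percent_of(884, 913, 1) # 96.8
percent_of <- function(count, denominator, digits = 2) {
  if (any(denominator == 0)) {
    stop_muac("denominator must be positive", "degenerate_input_error")
  }
  round_half_up(100 * count / denominator, digits)
}
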