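#' Configuration for the synthetic adolescent cohort generator
#'
#' The defaults emulate a school-based cohort of 884 girls aged 10-14
#' years: BAZ ~ Normal(-0.84, 1.30); mean MUAC 20.7 cm with total SD
#' 2.5 cm; a target population correlation of 0.80 between MUAC and
#' BAZ; MUAC rising about 0.9 cm per year of age; height about 150 cm
#' at age 12 growing 3.3 cm/yr; and small instrument error per
#' replicate measurement (MUAC 0.15 cm, height 0.3 cm, weight 0.1 kg).
#'
#' @param n cohort size.
#' @param age_months_range inclusive completed-month range, sampled
#'   discrete-uniform.
#' @param baz_mean,baz_sd latent BAZ distribution.
#' @param muac_mean mean true MUAC (cm) at the mid-range age.
#' @param muac_total_sd total SD of true MUAC (cm).
#' @param muac_age_slope cm of MUAC per year of age.
#' @param rho target population correlation between true MUAC and BAZ.
#' @param height_mean_at_12y,height_slope,height_sd height model (cm;
#'   slope per year; residual SD).
#' @param meas_error_sd named list of per-replicate instrument error
#'   SDs: muac_cm, height_cm, weight_kg.
#' @param seed master seed; independent substreams are derived from it
#'   per sampled quantity.
#' @return `cohort_config` list.
#' @export
cohort_config <- function(n = 884,
                          age_months_range = c(120L, 179L),
                          baz_mean = -0.84, baz_sd = 1.30,
                          muac_mean = 20.7, muac_total_sd = 2.5,
                          muac_age_slope = 0.9,
                          rho = 0.80,
                          height_mean_at_12y = 150, height_slope = 3.3,
                          height_sd = 6,
                          meas_error_sd = list(muac_cm = 0.15,
                                               height_cm = 0.3,
                                               weight_kg = 0.1),
                          seed = 1L) {
  if (n < 1) stop_muac("n must be >= 1", "configuration_error")
  if (baz_sd <= 0) stop_muac("baz_sd must be positive", "configuration_error")
  if (abs(rho) >= 1) stop_muac("rho must lie in (-1, 1)", "configuration_error")
  cfg <- list(n = as.integer(n),
              age_months_range = as.integer(age_months_range),
              baz_mean = baz_mean, baz_sd = baz_sd,
              muac_mean = muac_mean, muac_total_sd = muac_total_sd,
              muac_age_slope = muac_age_slope, rho = rho,
              height_mean_at_12y = height_mean_at_12y,
              height_slope = height_slope, height_sd = height_sd,
              meas_error_sd = meas_error_sd, seed = as.integer(seed))
  # fail fast: the correlation calibration must be feasible
  solve_muac_coefficients(rho, muac_total_sd, muac_age_slope, baz_sd,
                          age_sd_years(age_months_range))
  class(cfg) <- "cohort_config"
  cfg
}

age_sd_years <- function(range) {
  k <- diff(range) + 1
  sqrt((k^2 - 1) / 12) / 12
}

#' Solve the MUAC model coefficients for a target correlation
#'
#' Under the generative model
#' MUAC = beta0 + beta1 * age_c + b * z + e, with z independent of age,
#' choosing b = rho * total_sd / sigma_z and
#' sigma_e^2 = total_sd^2 - b^2 sigma_z^2 - beta1^2 sigma_age^2 makes
#' the population corr(MUAC, z) exactly `rho` and Var(MUAC) exactly
#' `total_sd^2`. Infeasible targets (sigma_e^2 < 0) raise a
#' configuration error naming the violated constraint.
#'
#' @param rho target correlation in (-1, 1).
#' @param total_sd total MUAC SD (cm).
#' @param beta1 age slope (cm per year).
#' @param sigma_z BAZ SD.
#' @param sigma_age SD of age in years.
#' @return list with `b` (cm per z-score unit) and `sigma_e` (residual
#'   SD, cm).
#' @export
solve_muac_coefficients <- function(rho, total_sd, beta1, sigma_z,
                                    sigma_age) {
  b <- rho * total_sd / sigma_z
  var_e <- total_sd^2 - b^2 * sigma_z^2 - beta1^2 * sigma_age^2
  if (var_e < 0) {
    stop_muac(sprintf(
      paste0("infeasible correlation target: rho^2*total_sd^2 + ",
             "beta1^2*sigma_age^2 = %.3f exceeds total_sd^2 = %.3f"),
      b^2 * sigma_z^2 + beta1^2 * sigma_age^2, total_sd^2),
      "configuration_error")
  }
  list(b = b, sigma_e = sqrt(var_e))
}

#' Generate a synthetic cohort with duplicate measurements
#'
#' Per girl: age in completed months is discrete-uniform over the study
#' window; latent BAZ is Normal; true MUAC follows the calibrated
#' linear model of [solve_muac_coefficients()]; height is linear in age
#' with Normal noise; BMI is the inverse LMS transform of the latent z
#' on the reference `table`, and weight follows from BMI and height.
#' Every instrument is then "measured" twice as truth + iid Normal
#' instrument error. The same seed yields an identical cohort.
#'
#' @param config `cohort_config`.
#' @param table `lms_table` used to map latent z to BMI (default the
#'   bundled [synthetic_lms()] fixture).
#' @return `synthetic_cohort` list: `records` (the cohort data frame in
#'   the schema [read_cohort()] expects) and `truth` (id, age_months,
#'   true_z, true_muac, true_category).
#' @export
generate_cohort <- function(config = cohort_config(),
                            table = synthetic_lms()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  rng <- config$age_months_range
  sol <- solve_muac_coefficients(config$rho, config$muac_total_sd,
                                 config$muac_age_slope, config$baz_sd,
                                 age_sd_years(rng))
  draw <- function(k, expr) {
    set.seed(substream_seed(config$seed, k))
    expr()
  }
  age_months <- draw(1L, function() sample(seq(rng[1], rng[2]), n, TRUE))
  z <- draw(2L, function() stats::rnorm(n, config$baz_mean, config$baz_sd))
  e <- draw(3L, function() stats::rnorm(n, 0, sol$sigma_e))
  h_noise <- draw(4L, function() stats::rnorm(n, 0, config$height_sd))
  age_yr <- age_months / 12
  age_c <- age_yr - mean(rng) / 12
  # centre on the BAZ mean so the cohort mean MUAC equals muac_mean
  true_muac <- config$muac_mean + config$muac_age_slope * age_c +
    sol$b * (z - config$baz_mean) + e
  true_height <- config$height_mean_at_12y +
    config$height_slope * (age_yr - 12) + h_noise
  row <- lms_lookup(table, age_months, sex = unique(table$sex)[1])
  true_bmi <- inverse_lms(z, row$L, row$M, row$S)
  true_weight <- true_bmi * (true_height / 100)^2

  meas <- function(truth, sd, k) {
    draw(k, function() truth + stats::rnorm(n, 0, sd))
  }
  esd <- config$meas_error_sd
  records <- data.frame(
    id = sprintf("g%04d", seq_len(n)),
    sex = "female",
    age_months = as.integer(age_months),
    school_type = "governmental",
    height_cm_rep1 = meas(true_height, esd$height_cm, 10L),
    height_cm_rep2 = meas(true_height, esd$height_cm, 11L),
    weight_kg_rep1 = meas(true_weight, esd$weight_kg, 12L),
    weight_kg_rep2 = meas(true_weight, esd$weight_kg, 13L),
    muac_cm_rep1 = meas(true_muac, esd$muac_cm, 14L),
    muac_cm_rep2 = meas(true_muac, esd$muac_cm, 15L),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    id = records$id, age_months = records$age_months,
    true_z = z, true_muac = true_muac,
    true_category = as.character(classify_baz(z)),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, seed = %d, rho target = %.2f\n",
              x$config$n, x$config$seed, x$config$rho))
  invisible(x)
}

#' Write a synthetic cohort (and its truth sidecar) to CSV
#'
#' @param cohort `synthetic_cohort`.
#' @param path cohort CSV (readable by [read_cohort()]).
#' @param truth_path optional sidecar CSV with the latent truth.
#' @return `path`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, path, truth_path = NULL) {
  utils::write.csv(cohort$records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Case/control values from a binormal model with known AUC
#'
#' Cases are Normal(mu0 - delta, sigma) and controls Normal(mu0, sigma)
#' with delta = sigma * sqrt(2) * qnorm(auc_target), so the population
#' AUC in the positive-if-low direction is exactly `auc_target`.
#'
#' @param auc_target population AUC in (0.5, 1).
#' @param prevalence case fraction in (0, 1); the case count is the
#'   rounded expectation.
#' @param n total sample size.
#' @param mean,sd control distribution parameters (defaults echo MUAC:
#'   21 cm, SD 2).
#' @param seed RNG seed.
#' @return data frame with `value` and logical `condition`.
#' @export
binormal_case_control <- function(auc_target, prevalence, n,
                                  mean = 21, sd = 2, seed = 1L) {
  if (auc_target <= 0.5 || auc_target >= 1) {
    stop_muac("auc_target must lie in (0.5, 1)", "configuration_error")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop_muac("prevalence must lie in (0, 1)", "configuration_error")
  }
  if (n < 2) stop_muac("n must be >= 2", "configuration_error")
  delta <- sd * sqrt(2) * stats::qnorm(auc_target)
  m <- max(1L, min(n - 1L, as.integer(round(n * prevalence))))
  set.seed(substream_seed(seed, 20L))
  data.frame(
    value = c(stats::rnorm(m, mean - delta, sd),
              stats::rnorm(n - m, mean, sd)),
    condition = rep(c(TRUE, FALSE), c(m, n - m))
  )
}
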