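#' Intra-observer technical error of measurement
#'
#' TEM = sqrt(sum(d_i^2) / (2n)) over duplicate pairs, the standard
#' absolute imprecision measure for anthropometry; for iid replicate
#' errors with SD sigma it estimates sigma. The relative TEM is
#' expressed as a percentage of the grand mean of all measurements.
#'
#' @param rep1,rep2 numeric vectors of first and second measurements.
#' @return `tem_result` list: tem, relative_tem_pct, scope, n_subjects,
#'   n_observers.
#' @export
#' @examples
#' intra_tem(c(10, 11), c(10.2, 10.8))$tem # 0.1414
intra_tem <- function(rep1, rep2) {
  if (length(rep1) != length(rep2)) {
    stop_muac("replicate vectors must have equal length", "domain_error")
  }
  keep <- !is.na(rep1) & !is.na(rep2)
  rep1 <- rep1[keep]; rep2 <- rep2[keep]
  n <- length(rep1)
  if (n < 2) stop_muac("need at least 2 complete pairs", "insufficient_data_error")
  tem <- sqrt(sum((rep1 - rep2)^2) / (2 * n))
  gm <- mean(c(rep1, rep2))
  if (gm == 0) stop_muac("grand mean is zero; relative TEM undefined",
                         "degenerate_input_error")
  structure(list(tem = tem, relative_tem_pct = 100 * tem / gm,
                 scope = "intra", n_subjects = n, n_observers = 2L),
            class = "tem_result")
}

#' Inter-observer technical error of measurement
#'
#' Multi-observer form TEM = sqrt( sum_i (sum_k x^2 - (sum_k x)^2 / k)
#' / (n (k - 1)) ) for an n subjects x k observers matrix; reduces to
#' the duplicate-pair formula at k = 2.
#'
#' @param m numeric matrix, one row per subject, one column per observer;
#'   must be complete.
#' @return `tem_result`.
#' @export
inter_tem <- function(m) {
  m <- as.matrix(m)
  if (any(is.na(m))) stop_muac("observer matrix must be complete",
                               "missing_data_error")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) {
    stop_muac("need >= 2 subjects and >= 2 observers",
              "insufficient_data_error")
  }
  ss <- rowSums(m^2) - rowSums(m)^2 / k
  tem <- sqrt(sum(ss) / (n * (k - 1)))
  gm <- mean(m)
  if (gm == 0) stop_muac("grand mean is zero; relative TEM undefined",
                         "degenerate_input_error")
  structure(list(tem = tem, relative_tem_pct = 100 * tem / gm,
                 scope = "inter", n_subjects = n, n_observers = k),
            class = "tem_result")
}

#' @export
print.tem_result <- function(x, ...) {
  cat(sprintf("%s-observer TEM: %.4f (relative %.2f%%), n = %d x %d\n",
              x$scope, x$tem, x$relative_tem_pct, x$n_subjects,
              x$n_observers))
  invisible(x)
}

#' Paired t test-retest comparison
#'
#' Two-sided paired t-test of first versus second measurement,
#' t = mean(d) / (sd(d)/sqrt(n)) with n - 1 degrees of freedom. With
#' zero variance of the differences the statistic is undefined and is
#' returned as NA with `degenerate = TRUE` rather than an error, so
#' perfectly repeated measurements can still be tabulated.
#'
#' @param m1,m2 equal-length numeric vectors.
#' @return `paired_test_result` list: t, df, p, n, mean_diff, degenerate.
#' @export
paired_ttest <- function(m1, m2) {
  if (length(m1) != length(m2)) {
    stop_muac("vectors must have equal length", "domain_error")
  }
  keep <- !is.na(m1) & !is.na(m2)
  m1 <- m1[keep]; m2 <- m2[keep]
  n <- length(m1)
  if (n < 2) stop_muac("need at least 2 pairs", "insufficient_data_error")
  d <- m1 - m2
  if (stats::sd(d) == 0) {
    return(structure(list(t = NA_real_, df = n - 1L, p = NA_real_, n = n,
                          mean_diff = mean(d), degenerate = TRUE),
                     class = "paired_test_result"))
  }
  tt <- stats::t.test(m1, m2, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n = n, mean_diff = unname(tt$estimate),
                 degenerate = FALSE),
            class = "paired_test_result")
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y equal-length numeric vectors, n >= 3, non-constant.
#' @param level confidence level (default 0.95).
#' @return `correlation_result` list: r, ci_low, ci_high, n, band
#'   (Cohen interpretation of |r|), level.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(y) != n) stop_muac("vectors must have equal length", "domain_error")
  if (n < 3) stop_muac("need at least 3 pairs", "insufficient_data_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_muac("correlation undefined for constant input",
              "undefined_correlation_error")
  }
  r <- stats::cor(x, y)
  if (abs(r) < 1 && n > 3) {
    zc <- stats::qnorm(1 - (1 - level) / 2)
    fz <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(c(fz - zc * se, fz + zc * se))
  } else {
    ci <- c(r, r)
  }
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], n = n,
                 band = cohen_band(r), level = level),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (%d%% CI %.3f-%.3f), n = %d, %s\n", x$r,
              round(100 * x$level), x$ci_low, x$ci_high, x$n, x$band))
  invisible(x)
}

#' Cohen interpretation band for a correlation
#'
#' |r| < 0.1 negligible; 0.1 <= |r| < 0.3 weak; 0.3 <= |r| < 0.5 medium;
#' 0.5 <= |r| <= 1 strong.
#'
#' @param r correlation in [-1, 1].
#' @return character band.
#' @export
#' @examples
#' cohen_band(0.80) # "strong"
cohen_band <- function(r) {
  if (any(abs(r) > 1)) stop_muac("|r| must not exceed 1", "domain_error")
  a <- abs(r)
  ifelse(a < 0.1, "negligible",
         ifelse(a < 0.3, "weak", ifelse(a < 0.5, "medium", "strong")))
}
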