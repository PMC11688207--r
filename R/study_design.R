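#' Sample size for a diagnostic accuracy study
#'
#' Buderer-style formulas: the size needed to estimate sensitivity to
#' absolute precision L at prevalence P,
#' N1 = ceil(z^2 SN(1-SN) / (L^2 P)), and specificity,
#' N2 = ceil(z^2 SP(1-SP) / (L^2 (1-P))). The base size is the larger
#' of the two, then inflated by the design effect for multistage
#' sampling and by the anticipated non-response.
#'
#' @param sensitivity,specificity anticipated SN and SP in (0, 1).
#' @param prevalence anticipated condition prevalence P in (0, 1).
#' @param precision absolute half-width L of the CI, in (0, 0.5].
#' @param alpha two-sided significance level (z = qnorm(1 - alpha/2)).
#' @param design_effect multiplicative inflation >= 1 for clustered
#'   sampling.
#' @param nonresponse_rate anticipated non-response fraction in [0, 1).
#' @param nonresponse_inflation `"multiplicative"` (x (1 + rate),
#'   default) or `"divisive"` (/ (1 - rate)).
#' @return `design_result` list: n_sens, n_spec, n_base, n_final and the
#'   inputs.
#' @export
#' @examples
#' diag_sample_size(0.94, 0.79, prevalence = 0.213, precision = 0.05,
#'                  design_effect = 2, nonresponse_rate = 0.10)
diag_sample_size <- function(sensitivity, specificity, prevalence,
                             precision = 0.05, alpha = 0.05,
                             design_effect = 1, nonresponse_rate = 0,
                             nonresponse_inflation = c("multiplicative",
                                                       "divisive")) {
  nonresponse_inflation <- match.arg(nonresponse_inflation)
  for (p in c(sensitivity, specificity)) {
    if (p <= 0 || p >= 1) stop_muac("SN and SP must lie in (0, 1)",
                                    "domain_error")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop_muac("prevalence must lie strictly in (0, 1)", "division_error")
  }
  if (precision <= 0 || precision > 0.5) {
    stop_muac("precision must lie in (0, 0.5]", "domain_error")
  }
  if (design_effect < 1) stop_muac("design effect must be >= 1", "domain_error")
  if (nonresponse_rate < 0 || nonresponse_rate >= 1) {
    stop_muac("non-response rate must lie in [0, 1)", "domain_error")
  }
  z <- stats::qnorm(1 - alpha / 2)
  n1 <- ceiling(z^2 * sensitivity * (1 - sensitivity) /
                  (precision^2 * prevalence))
  n2 <- ceiling(z^2 * specificity * (1 - specificity) /
                  (precision^2 * (1 - prevalence)))
  base <- max(n1, n2)
  final <- if (nonresponse_inflation == "multiplicative") {
    ceiling(base * design_effect * (1 + nonresponse_rate))
  } else {
    ceiling(base * design_effect / (1 - nonresponse_rate))
  }
  structure(list(n_sens = as.integer(n1), n_spec = as.integer(n2),
                 n_base = as.integer(base), n_final = as.integer(final),
                 inputs = list(sensitivity = sensitivity,
                               specificity = specificity,
                               prevalence = prevalence,
                               precision = precision, alpha = alpha,
                               design_effect = design_effect,
                               nonresponse_rate = nonresponse_rate,
                               nonresponse_inflation = nonresponse_inflation)),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf(
    "N1 (sensitivity) = %d, N2 (specificity) = %d, base = %d, final = %d\n",
    x$n_sens, x$n_spec, x$n_base, x$n_final))
  invisible(x)
}
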