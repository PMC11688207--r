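#' 2x2 confusion counts at a cutoff
#'
#' With direction `"positive_if_low"` (the MUAC convention: a small arm
#' circumference flags thinness) a value is test-positive when
#' value <= cutoff; the boundary value counts positive, matching
#' report-table "<=" cutoffs. `"positive_if_high"` flips the rule to
#' value >= cutoff.
#'
#' @param values numeric test values (finite).
#' @param condition logical vector, TRUE = has the reference condition.
#' @param cutoff numeric threshold.
#' @param direction `"positive_if_low"` or `"positive_if_high"`.
#' @return `confusion_counts` list: tp, fp, fn, tn.
#' @export
confusion_at <- function(values, condition,
                         cutoff, direction = c("positive_if_low",
                                               "positive_if_high")) {
  direction <- match.arg(direction)
  if (length(values) == 0) stop_muac("empty data", "degenerate_input_error")
  if (length(values) != length(condition)) {
    stop_muac("values and condition must have equal length", "domain_error")
  }
  pos <- if (direction == "positive_if_low") values <= cutoff
         else values >= cutoff
  structure(list(tp = sum(pos & condition), fp = sum(pos & !condition),
                 fn = sum(!pos & condition), tn = sum(!pos & !condition)),
            class = "confusion_counts")
}

#' Sensitivity and specificity
#' @param cc `confusion_counts`.
#' @return list with sn = tp/(tp+fn) and sp = tn/(fp+tn).
#' @export
sens_spec <- function(cc) {
  if (cc$tp + cc$fn == 0 || cc$fp + cc$tn == 0) {
    stop_muac("need at least one case and one control", "undefined_metric_error")
  }
  list(sn = cc$tp / (cc$tp + cc$fn), sp = cc$tn / (cc$fp + cc$tn))
}

#' Positive likelihood ratio
#'
#' sn / (1 - sp); infinite when specificity is 1 (report tables print
#' a dash there).
#'
#' @param sn,sp sensitivity and specificity in [0, 1].
#' @return ratio (Inf when sp = 1).
#' @export
#' @examples
#' plr(0.95, 0.814) # 5.11
plr <- function(sn, sp) {
  check_prob(sn, sp)
  ifelse(sp == 1, Inf, sn / (1 - sp))
}

#' Negative likelihood ratio
#'
#' (1 - sn) / sp; undefined when specificity is 0.
#'
#' @inheritParams plr
#' @return ratio.
#' @export
#' @examples
#' nlr(0.921, 0.673) # 0.117
nlr <- function(sn, sp) {
  check_prob(sn, sp)
  if (any(sp == 0)) stop_muac("NLR undefined at specificity 0",
                              "undefined_metric_error")
  (1 - sn) / sp
}

#' Youden's J
#'
#' J = sensitivity + specificity - 1; 1 for a perfect test, 0 for a
#' worthless one.
#'
#' @inheritParams plr
#' @return J.
#' @export
#' @examples
#' youden(0.908, 0.759) # 0.667
youden <- function(sn, sp) {
  check_prob(sn, sp)
  sn + sp - 1
}

check_prob <- function(sn, sp) {
  if (any(sn < 0 | sn > 1 | sp < 0 | sp > 1)) {
    stop_muac("sensitivity and specificity must lie in [0, 1]",
              "domain_error")
  }
}

#' Predictive values
#'
#' ppv = tp/(tp+fp), npv = tn/(fn+tn); an empty margin yields NA rather
#' than an error so degenerate cutoffs can still be tabulated.
#'
#' @param cc `confusion_counts`.
#' @return list with ppv and npv (NA where undefined).
#' @export
predictive_values <- function(cc) {
  list(ppv = if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_,
       npv = if (cc$fn + cc$tn > 0) cc$tn / (cc$fn + cc$tn) else NA_real_)
}

#' Clopper-Pearson exact binomial interval
#'
#' Exact interval from beta quantiles: lo = qbeta(a/2, k, n-k+1),
#' hi = qbeta(1-a/2, k+1, n-k), with lo = 0 at k = 0 and hi = 1 at
#' k = n.
#'
#' @param k successes, 0 <= k <= n.
#' @param n trials, n >= 1.
#' @param level confidence level (default 0.95).
#' @return numeric c(lo, hi).
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n) stop_muac("need 0 <= k <= n, n >= 1",
                                         "domain_error")
  a <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  c(lo, hi)
}

#' Log-method confidence intervals for likelihood ratios
#'
#' exp(log LR +/- z * se) with
#' se_PLR = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)) and
#' se_NLR = sqrt(1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn)). A zero cell
#' makes the corresponding interval undefined; it is returned as NAs
#' with a flag instead of an error.
#'
#' @param cc `confusion_counts`.
#' @param level confidence level.
#' @return list of `plr` and `nlr`, each c(estimate, lo, hi), plus
#'   `plr_flagged`/`nlr_flagged` logicals.
#' @export
lr_ci <- function(cc, level = 0.95) {
  ss <- sens_spec(cc)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- plr(ss$sn, ss$sp)
  nl <- if (ss$sp > 0) nlr(ss$sn, ss$sp) else NA_real_
  plr_ok <- cc$tp > 0 && cc$fp > 0
  nlr_ok <- cc$fn > 0 && cc$tn > 0
  pint <- if (plr_ok) {
    se <- sqrt(1 / cc$tp - 1 / (cc$tp + cc$fn) + 1 / cc$fp -
               1 / (cc$fp + cc$tn))
    exp(log(p) + c(-1, 1) * z * se)
  } else c(NA_real_, NA_real_)
  nint <- if (nlr_ok && !is.na(nl) && nl > 0) {
    se <- sqrt(1 / cc$fn - 1 / (cc$tp + cc$fn) + 1 / cc$tn -
               1 / (cc$fp + cc$tn))
    exp(log(nl) + c(-1, 1) * z * se)
  } else c(NA_real_, NA_real_)
  list(plr = c(estimate = p, lo = pint[1], hi = pint[2]),
       nlr = c(estimate = nl, lo = nint[1], hi = nint[2]),
       plr_flagged = !plr_ok, nlr_flagged = !(nlr_ok && !is.na(nl) && nl > 0))
}

#' ROC curve over all observed thresholds
#'
#' One operating point per distinct observed value plus the two
#' degenerate sentinels (nobody positive: sn = 0, sp = 1; everybody
#' positive: sn = 1, sp = 0). The AUC is the trapezoidal area over
#' (1 - sp, sn), which equals the tie-corrected Mann-Whitney statistic
#' (ties counted one half).
#'
#' @inheritParams confusion_at
#' @return `roc_curve` object: data frame `points` (threshold, sn, sp),
#'   `auc`, `direction`, `n_cases`, `n_controls`, and the input data.
#' @export
roc_curve <- function(values, condition,
                      direction = c("positive_if_low", "positive_if_high")) {
  direction <- match.arg(direction)
  condition <- as.logical(condition)
  if (any(!is.finite(values))) stop_muac("values must be finite", "domain_error")
  m <- sum(condition); n0 <- sum(!condition)
  if (m == 0 || n0 == 0) {
    stop_muac("need at least one case and one control", "degenerate_roc_error")
  }
  s <- if (direction == "positive_if_low") 1 else -1
  v <- s * values  # positive test iff v <= s * cutoff
  thr <- sort(unique(v))
  # counts of cases/controls at or below each distinct value
  case_cum <- cumsum(tabulate(match(v[condition], thr), length(thr)))
  ctrl_cum <- cumsum(tabulate(match(v[!condition], thr), length(thr)))
  sn <- c(0, case_cum / m, 1)
  sp <- c(1, 1 - ctrl_cum / n0, 0)
  points <- data.frame(threshold = s * c(-Inf, thr, Inf), sn = sn, sp = sp)
  fpr <- 1 - sp
  o <- order(fpr, sn)
  auc <- sum(diff(fpr[o]) * (utils::head(sn[o], -1) + utils::tail(sn[o], -1)) / 2)
  structure(list(points = points, auc = auc, direction = direction,
                 n_cases = m, n_controls = n0,
                 values = values, condition = condition),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d cases / %d controls, %s, AUC = %.3f\n",
              x$n_cases, x$n_controls, x$direction, x$auc))
  invisible(x)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from case and control
#' placement values; the interval is truncated to [0, 1]. Degenerate
#' data (all values tied, or a placement variance of zero at AUC 1)
#' yields a flagged interval.
#'
#' @inheritParams confusion_at
#' @param level confidence level.
#' @return list: auc, lo, hi, se, level, flagged.
#' @export
auc_ci <- function(values, condition,
                   direction = c("positive_if_low", "positive_if_high"),
                   level = 0.95) {
  direction <- match.arg(direction)
  condition <- as.logical(condition)
  m <- sum(condition); n0 <- sum(!condition)
  if (m == 0 || n0 == 0) {
    stop_muac("need at least one case and one control", "degenerate_roc_error")
  }
  # score oriented so that larger = more case-like
  x <- if (direction == "positive_if_low") -values[condition]
       else values[condition]
  y <- if (direction == "positive_if_low") -values[!condition]
       else values[!condition]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  theta <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  s10 <- if (m > 1) stats::var(v10) else NA_real_
  s01 <- if (n0 > 1) stats::var(v01) else NA_real_
  se <- sqrt(s10 / m + s01 / n0)
  flagged <- !is.finite(se) || se == 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- if (flagged) c(theta, theta) else
    pmin(1, pmax(0, theta + c(-1, 1) * z * se))
  list(auc = theta, lo = ci[1], hi = ci[2], se = se, level = level,
       flagged = flagged)
}

#' Accuracy band for an AUC
#'
#' excellent 0.9-1 (closed at 1), good 0.8-0.9, fair 0.7-0.8, poor
#' 0.6-0.7, fail below 0.6.
#'
#' @param auc AUC in [0, 1].
#' @return character band.
#' @export
#' @examples
#' auc_band(0.86) # "good"
auc_band <- function(auc) {
  if (any(auc < 0 | auc > 1)) stop_muac("AUC must lie in [0, 1]", "domain_error")
  ifelse(auc >= 0.9, "excellent",
         ifelse(auc >= 0.8, "good",
                ifelse(auc >= 0.7, "fair",
                       ifelse(auc >= 0.6, "poor", "fail"))))
}

#' Youden-optimal cutoff with the full diagnostic metric set
#'
#' Scans every threshold of the ROC curve for the maximum of
#' J = sn + sp - 1. Ties are broken by higher sensitivity, then by the
#' smaller cutoff value (the more conservative screening threshold in
#' the positive-if-low direction). At the winning cutoff the complete
#' 2x2 metric set is computed: sensitivity, specificity, predictive
#' values and accuracy with Clopper-Pearson intervals, likelihood
#' ratios with log-method intervals.
#'
#' @param roc `roc_curve` object.
#' @param level confidence level for all intervals.
#' @return `diagnostic_summary` list.
#' @export
optimal_cutoff <- function(roc, level = 0.95) {
  if (!inherits(roc, "roc_curve")) stop_muac("expected a roc_curve object",
                                             "domain_error")
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  if (nrow(pts) == 0) stop_muac("degenerate curve", "degenerate_roc_error")
  j <- pts$sn + pts$sp - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[pts$sn[best] == max(pts$sn[best])]
  if (length(best) > 1) {
    best <- if (roc$direction == "positive_if_low")
      best[which.min(pts$threshold[best])]
    else best[which.max(pts$threshold[best])]
  }
  cutoff <- pts$threshold[best]
  cc <- confusion_at(roc$values, roc$condition, cutoff, roc$direction)
  summarize_cutoff(cc, cutoff, roc, level)
}

summarize_cutoff <- function(cc, cutoff, roc, level = 0.95) {
  ss <- sens_spec(cc)
  pv <- predictive_values(cc)
  lr <- lr_ci(cc, level)
  n <- cc$tp + cc$fp + cc$fn + cc$tn
  acc <- (cc$tp + cc$tn) / n
  aci <- auc_ci(roc$values, roc$condition, roc$direction, level)
  structure(list(
    cutoff = cutoff,
    direction = roc$direction,
    counts = cc,
    n = n,
    prevalence = (cc$tp + cc$fn) / n,
    sn = ss$sn, sn_ci = clopper_pearson(cc$tp, cc$tp + cc$fn, level),
    sp = ss$sp, sp_ci = clopper_pearson(cc$tn, cc$fp + cc$tn, level),
    ppv = pv$ppv,
    ppv_ci = if (cc$tp + cc$fp > 0)
      clopper_pearson(cc$tp, cc$tp + cc$fp, level) else c(NA_real_, NA_real_),
    npv = pv$npv,
    npv_ci = if (cc$fn + cc$tn > 0)
      clopper_pearson(cc$tn, cc$fn + cc$tn, level) else c(NA_real_, NA_real_),
    plr = unname(lr$plr["estimate"]), plr_ci = unname(lr$plr[c("lo", "hi")]),
    nlr = unname(lr$nlr["estimate"]), nlr_ci = unname(lr$nlr[c("lo", "hi")]),
    accuracy_pct = 100 * acc,
    accuracy_ci = 100 * clopper_pearson(cc$tp + cc$tn, n, level),
    youden = ss$sn + ss$sp - 1,
    auc = aci$auc, auc_ci = c(aci$lo, aci$hi), auc_band = auc_band(aci$auc),
    auc_flagged = aci$flagged,
    level = level
  ), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  fmt_pct <- function(p, ci) sprintf("%.1f%% (%.1f-%.1f)", 100 * p,
                                     100 * ci[1], 100 * ci[2])
  cat(sprintf("Optimal cutoff (Youden): value %s %.1f\n",
              if (x$direction == "positive_if_low") "<=" else ">=", x$cutoff))
  cat(sprintf("  AUC  %.2f (%.2f-%.2f) [%s]\n", x$auc, x$auc_ci[1],
              x$auc_ci[2], x$auc_band))
  cat("  SN  ", fmt_pct(x$sn, x$sn_ci), "\n")
  cat("  SP  ", fmt_pct(x$sp, x$sp_ci), "\n")
  cat(sprintf("  PLR  %.2f  NLR  %.2f  J  %.2f\n", x$plr, x$nlr, x$youden))
  cat("  PPV ", fmt_pct(x$ppv, x$ppv_ci), " NPV ", fmt_pct(x$npv, x$npv_ci),
      "\n")
  cat(sprintf("  Correctly classified %.1f%%\n", x$accuracy_pct))
  invisible(x)
}
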