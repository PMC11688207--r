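test_that("confusion counts treat the cutoff as inclusive for positive-if-low", {
  v <- c(18, 19, 22, 23); cond <- c(TRUE, TRUE, FALSE, FALSE)
  cc <- confusion_at(v, cond, 20)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 0L, fn = 0L, tn = 2L))
  cc19 <- confusion_at(v, cond, 19)
  expect_equal(cc19$tp, 2L)  # 19 <= 19 counts positive
  expect_equal(cc19$fp, 0L)
  cc3 <- confusion_at(c(18, 21, 19, 23), c(TRUE, TRUE, FALSE, FALSE), 20)
  expect_equal(unclass(cc3)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_error(confusion_at(numeric(), logical(), 1),
               class = "degenerate_input_error")
})

test_that("sensitivity/specificity and predictive values are the 2x2 ratios", {
  cc <- structure(list(tp = 9, fp = 3, fn = 1, tn = 17),
                  class = "confusion_counts")
  ss <- sens_spec(cc)
  expect_equal(ss$sn, 0.9)
  expect_equal(ss$sp, 0.85)
  pv <- predictive_values(structure(list(tp = 1, fp = 3, fn = 0, tn = 6),
                                    class = "confusion_counts"))
  expect_equal(pv$ppv, 0.25)
  expect_equal(pv$npv, 1.0)
  pv0 <- predictive_values(structure(list(tp = 0, fp = 0, fn = 1, tn = 9),
                                     class = "confusion_counts"))
  expect_true(is.na(pv0$ppv))
  expect_equal(pv0$npv, 0.9)
})

test_that("likelihood ratios and Youden's J match the printed identities", {
  expect_equal(round_half_up(plr(0.95, 0.814), 2), 5.11)
  expect_equal(plr(1.0, 0.5), 2.0)
  expect_equal(plr(0.9, 1.0), Inf)
  expect_equal(round_half_up(nlr(0.921, 0.673), 2), 0.12)
  expect_equal(round_half_up(nlr(1.0, 0.859), 2), 0.00)
  expect_equal(round_half_up(nlr(0.959, 0.685), 2), 0.06)
  expect_equal(round_half_up(youden(0.908, 0.759), 2), 0.67)
  expect_equal(youden(1, 1), 1)
  expect_equal(round_half_up(youden(0.871, 0.904), 2), 0.78)
  expect_error(nlr(0.9, 0), class = "undefined_metric_error")
})

test_that("Clopper-Pearson matches closed forms and binom.test", {
  expect_equal(clopper_pearson(10, 10)[2], 1)
  expect_equal(clopper_pearson(0, 10)[1], 0)
  expect_equal(clopper_pearson(0, 10)[2], 1 - 0.025^(1 / 10),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:80, 1); k <- sample(0:n, 1)
    expect_equal(clopper_pearson(k, n),
                 as.numeric(binom.test(k, n)$conf.int), tolerance = 1e-9)
  }
  expect_equal(clopper_pearson(5, 10), c(0.187, 0.813), tolerance = 1e-3)
  expect_error(clopper_pearson(11, 10), class = "domain_error")
})

test_that("log-method LR intervals contain the estimate and flag zero cells", {
  cc <- structure(list(tp = 9, fp = 3, fn = 1, tn = 17),
                  class = "confusion_counts")
  lr <- lr_ci(cc)
  expect_equal(unname(lr$plr["estimate"]), 6.0)
  expect_true(lr$plr["lo"] < 6 && 6 < lr$plr["hi"])
  sym <- lr_ci(structure(list(tp = 5, fp = 5, fn = 5, tn = 5),
                         class = "confusion_counts"))
  expect_equal(unname(sym$plr["estimate"]), 1)
  expect_true(sym$plr["lo"] < 1 && 1 < sym$plr["hi"])
  z <- lr_ci(structure(list(tp = 0, fp = 2, fn = 5, tn = 5),
                       class = "confusion_counts"))
  expect_equal(unname(z$plr["estimate"]), 0)
  expect_true(z$plr_flagged)
})

test_that("trapezoidal AUC equals the tie-corrected Mann-Whitney statistic", {
  perfect <- roc_curve(c(17, 18, 22, 23), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  tied <- roc_curve(rep(20, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(tied$auc, 0.5)
  expect_equal(roc_curve(c(1, 2, 3, 2, 3, 4),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc,
               7 / 9)  # exhaustive pairwise count: (3 + 2.5 + 1.5)/9

  set.seed(12)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    vals <- sample(seq(15, 25, by = 0.5), n, replace = TRUE)
    cond <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(cond) || all(cond)) next
    expect_equal(roc_curve(vals, cond)$auc, mw_auc(vals, cond),
                 tolerance = 1e-12)
  }
})

test_that("reversing the direction maps AUC to 1 - AUC", {
  set.seed(3)
  vals <- rnorm(60, 20, 2)
  cond <- rbinom(60, 1, 0.3) == 1
  a <- roc_curve(vals, cond, "positive_if_low")$auc
  b <- roc_curve(vals, cond, "positive_if_high")$auc
  expect_equal(a + b, 1, tolerance = 1e-12)
  expect_error(roc_curve(vals, rep(TRUE, 60)), class = "degenerate_roc_error")
})

test_that("DeLong intervals agree with pROC and cover degenerate cases", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:5) {
    vals <- rnorm(80, 20, 2)
    cond <- c(rep(TRUE, 25), rep(FALSE, 55))
    vals[cond] <- vals[cond] - 2
    mine <- auc_ci(vals, cond, "positive_if_low")
    ref <- pROC::ci.auc(pROC::roc(cond, vals, direction = ">",
                                  quiet = TRUE), method = "delong")
    expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-9)
    expect_equal(c(mine$lo, mine$hi), as.numeric(ref[c(1, 3)]),
                 tolerance = 1e-9)
  }
  tied <- auc_ci(rep(20, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_true(tied$lo <= 0.5 && 0.5 <= tied$hi)
  sep <- auc_ci(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$hi, 1)
})

test_that("DeLong intervals reach near-nominal coverage on binormal data", {
  set.seed(77)
  target <- 0.8
  delta <- sqrt(2) * qnorm(target)
  hits <- 0; reps <- 200
  for (i in 1:reps) {
    d <- binormal_case_control(target, 0.3, 300, seed = i)
    ci <- auc_ci(d$value, d$condition)
    hits <- hits + (ci$lo <= target && target <= ci$hi)
  }
  expect_gte(hits / reps, 0.90)
})

test_that("AUC accuracy bands follow the stated cutpoints", {
  expect_equal(auc_band(0.86), "good")
  expect_equal(auc_band(0.95), "excellent")
  expect_equal(auc_band(c(0.9, 0.8, 0.7, 0.6, 0.55, 1)),
               c("excellent", "good", "fair", "poor", "fail", "excellent"))
  expect_error(auc_band(1.2), class = "domain_error")
})

test_that("the Youden-optimal cutoff maximises J with the stated tie rules", {
  roc <- roc_curve(c(18, 19, 19.5, 19.5, 21, 22, 23),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  s <- optimal_cutoff(roc)
  expect_equal(s$cutoff, 19.5)
  expect_equal(s$sn, 1)
  expect_equal(s$sp, 0.75)
  expect_equal(s$youden, 0.75)

  # perfect separation: J = 1 at a cutoff between the classes
  p <- optimal_cutoff(roc_curve(c(17, 18, 22, 23),
                                c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(p$youden, 1)
  expect_gte(p$cutoff, 18)
  expect_lt(p$cutoff, 22)

  # J from the chosen cutoff dominates every enumerated threshold
  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    vals <- sample(seq(16, 26, by = 0.5), n, replace = TRUE)
    cond <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(cond) || all(cond)) next
    r <- roc_curve(vals, cond)
    best <- optimal_cutoff(r)
    for (t in unique(vals)) {
      cc <- confusion_at(vals, cond, t)
      ss <- sens_spec(cc)
      expect_lte(ss$sn + ss$sp - 1, best$youden + 1e-12)
    }
  }
})

test_that("ties in J break by sensitivity, then by the smaller cutoff", {
  # thresholds 18 and 20 both give J = 0.5; 20 has the higher sn
  vals <- c(18, 20, 19, 21)
  cond <- c(TRUE, TRUE, FALSE, FALSE)
  # at 18: sn=.5, sp=1, J=.5; at 20: sn=1, sp=.5, J=.5 -> pick 20 (sn rule)
  s <- optimal_cutoff(roc_curve(vals, cond))
  expect_equal(s$cutoff, 20)
  expect_equal(s$sn, 1)
})

test_that("accuracy equals the prevalence-weighted sn/sp mix", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    vals <- rnorm(n, 20, 2)
    cond <- rbinom(n, 1, 0.4) == 1
    if (!any(cond) || all(cond)) next
    s <- optimal_cutoff(roc_curve(vals, cond))
    prev <- s$prevalence
    expect_equal(s$accuracy_pct,
                 100 * (s$sn * prev + s$sp * (1 - prev)), tolerance = 1e-9)
  }
})
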