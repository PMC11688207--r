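#' Built-in screening conditions on the BMI-for-age z-score
#'
#' Four case/control definitions:
#' * `thinness_incl_severe`: case z < -2, control z >= -2
#' * `severe_thinness`: case z < -3, control z >= -3
#' * `thinness_only`: case -3 <= z < -2; by default severely thin girls
#'   are excluded from both groups (controls z >= -2); with
#'   `thinness_only_excludes_severe = FALSE` they are counted among the
#'   cases, making the condition identical to `thinness_incl_severe`
#' * `overweight_incl_obesity`: case z > +1, control z <= +1
#'
#' @param thinness_only_excludes_severe see above.
#' @return named list of condition specs, each with `name`, `case` and
#'   `control` predicate functions on z.
#' @export
builtin_conditions <- function(thinness_only_excludes_severe = TRUE) {
  spec <- function(name, case, control) {
    list(name = name, case = case, control = control)
  }
  thin_case <- if (thinness_only_excludes_severe) {
    function(z) z >= -3 & z < -2
  } else {
    function(z) z < -2
  }
  list(
    thinness_incl_severe = spec("thinness_incl_severe",
                                function(z) z < -2, function(z) z >= -2),
    severe_thinness = spec("severe_thinness",
                           function(z) z < -3, function(z) z >= -3),
    thinness_only = spec("thinness_only", thin_case, function(z) z >= -2),
    overweight_incl_obesity = spec("overweight_incl_obesity",
                                   function(z) z > 1, function(z) z <= 1)
  )
}

#' Run the full MUAC screening-accuracy analysis
#'
#' Reads and validates the cohort, averages duplicate measurements,
#' computes BMI-for-age z-scores against the supplied LMS reference,
#' then per condition and per age stratum (completed years 10..14 plus
#' the pooled sample) builds the MUAC ROC curve and the Youden-optimal
#' cutoff summary. Also produces the descriptive mean/SD table, the
#' MUAC test-retest reliability table (paired t and TEM), the pooled
#' and age-specific MUAC-BAZ correlations, and per-age category counts.
#' Strata without both a case and a control are flagged not estimable
#' and the run continues. The analysis is fully deterministic.
#'
#' @param cohort_path cohort CSV (schema of [read_cohort()]).
#' @param lms_path LMS reference CSV, or an `lms_table` object.
#' @param conditions list from [builtin_conditions()].
#' @param schema column mapping for the cohort file.
#' @param level confidence level for all intervals.
#' @param sex sex level in the LMS table.
#' @return `report_bundle` list: summary, reliability, correlations,
#'   correlations_by_age, categories, diagnostics (one data frame per
#'   condition), roc (nested list of `roc_curve`s), rejects, log.
#' @export
run_analysis <- function(cohort_path, lms_path,
                         conditions = builtin_conditions(),
                         schema = cohort_schema(), level = 0.95,
                         sex = "female") {
  cohort <- read_cohort(cohort_path, schema)
  table <- if (inherits(lms_path, "lms_table")) lms_path else read_lms(lms_path)
  avg <- average_cohort(cohort)
  scored <- baz(avg, table, sex = sex)
  log <- c(sprintf("validated records: %d (rejected rows: %d)",
                   nrow(scored), length(unique(cohort$rejects$id))))

  strata <- c(sort(unique(scored$age_years)), NA)  # NA = pooled
  stratum_label <- function(a) if (is.na(a)) "pooled" else as.character(a)
  in_stratum <- function(a) if (is.na(a)) rep(TRUE, nrow(scored))
                            else scored$age_years == a

  # Table-2-style descriptive summary
  summary_tab <- do.call(rbind, lapply(strata, function(a) {
    s <- scored[in_stratum(a), ]
    data.frame(stratum = stratum_label(a), n = nrow(s),
               weight_mean = mean(s$weight_kg), weight_sd = stats::sd(s$weight_kg),
               height_mean = mean(s$height_cm), height_sd = stats::sd(s$height_cm),
               muac_mean = mean(s$muac_cm), muac_sd = stats::sd(s$muac_cm),
               baz_mean = mean(s$z), baz_sd = stats::sd(s$z),
               stringsAsFactors = FALSE)
  }))

  # test-retest reliability of the duplicate MUAC measurements
  rec <- cohort$records
  rec_age <- age_years(rec$age_months)
  reliability <- do.call(rbind, lapply(strata, function(a) {
    idx <- if (is.na(a)) rep(TRUE, nrow(rec)) else rec_age == a
    m1 <- rec$muac_cm_rep1[idx]; m2 <- rec$muac_cm_rep2[idx]
    tt <- paired_ttest(m1, m2)
    tem <- intra_tem(m1, m2)
    data.frame(stratum = stratum_label(a), n = tt$n,
               muac1_mean = mean(m1, na.rm = TRUE),
               muac1_sd = stats::sd(m1, na.rm = TRUE),
               muac2_mean = mean(m2, na.rm = TRUE),
               muac2_sd = stats::sd(m2, na.rm = TRUE),
               t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate,
               tem = tem$tem, relative_tem_pct = tem$relative_tem_pct,
               stringsAsFactors = FALSE)
  }))

  # correlations: pooled MUAC~BAZ and MUAC~age, per-age MUAC~BAZ
  corr_row <- function(label, x, y) {
    cr <- pearson_ci(x, y, level)
    data.frame(characteristic = label, r = cr$r, ci_low = cr$ci_low,
               ci_high = cr$ci_high, n = cr$n, band = cr$band,
               stringsAsFactors = FALSE)
  }
  correlations <- rbind(
    corr_row("baz", scored$muac_cm, scored$z),
    corr_row("age_years", scored$muac_cm, scored$age_years)
  )
  correlations_by_age <- do.call(rbind, lapply(strata[!is.na(strata)],
    function(a) {
      s <- scored[in_stratum(a), ]
      cbind(stratum = as.character(a), corr_row("baz", s$muac_cm, s$z))
    }))

  categories <- as.data.frame(table(stratum = scored$age_years,
                                    category = scored$category),
                              stringsAsFactors = FALSE)
  names(categories)[3] <- "count"

  diagnostics <- list(); roc_store <- list()
  for (cname in names(conditions)) {
    cond <- conditions[[cname]]
    rows <- list(); roc_store[[cname]] <- list()
    for (a in strata) {
      s <- scored[in_stratum(a), ]
      is_case <- cond$case(s$z); is_ctrl <- cond$control(s$z)
      keep <- is_case | is_ctrl
      lab <- stratum_label(a)
      if (sum(is_case) < 1 || sum(is_ctrl) < 1) {
        rows[[lab]] <- diag_row(lab, sum(keep), sum(is_case), NULL)
        log <- c(log, sprintf("%s / %s: not estimable (%d cases, %d controls)",
                              cname, lab, sum(is_case), sum(is_ctrl)))
        next
      }
      roc <- roc_curve(s$muac_cm[keep], is_case[keep], "positive_if_low")
      roc_store[[cname]][[lab]] <- roc
      summ <- optimal_cutoff(roc, level)
      rows[[lab]] <- diag_row(lab, sum(keep), sum(is_case), summ)
    }
    diagnostics[[cname]] <- do.call(rbind, rows)
  }

  structure(list(summary = summary_tab, reliability = reliability,
                 correlations = correlations,
                 correlations_by_age = correlations_by_age,
                 categories = categories, diagnostics = diagnostics,
                 roc = roc_store, rejects = cohort$rejects, log = log,
                 level = level),
            class = "report_bundle")
}

diag_row <- function(stratum, n, n_cases, s) {
  if (is.null(s)) {
    return(data.frame(stratum = stratum, n = n, cases = n_cases,
                      estimable = FALSE, cutoff = NA_real_, auc = NA_real_,
                      auc_lo = NA_real_, auc_hi = NA_real_,
                      auc_band = NA_character_, sn = NA_real_,
                      sn_lo = NA_real_, sn_hi = NA_real_, sp = NA_real_,
                      sp_lo = NA_real_, sp_hi = NA_real_, plr = NA_real_,
                      plr_lo = NA_real_, plr_hi = NA_real_, nlr = NA_real_,
                      nlr_lo = NA_real_, nlr_hi = NA_real_, ppv = NA_real_,
                      ppv_lo = NA_real_, ppv_hi = NA_real_, npv = NA_real_,
                      npv_lo = NA_real_, npv_hi = NA_real_,
                      accuracy_pct = NA_real_, youden = NA_real_,
                      stringsAsFactors = FALSE))
  }
  data.frame(stratum = stratum, n = n, cases = n_cases, estimable = TRUE,
             cutoff = s$cutoff, auc = s$auc, auc_lo = s$auc_ci[1],
             auc_hi = s$auc_ci[2], auc_band = s$auc_band, sn = s$sn,
             sn_lo = s$sn_ci[1], sn_hi = s$sn_ci[2], sp = s$sp,
             sp_lo = s$sp_ci[1], sp_hi = s$sp_ci[2], plr = s$plr,
             plr_lo = s$plr_ci[1], plr_hi = s$plr_ci[2], nlr = s$nlr,
             nlr_lo = s$nlr_ci[1], nlr_hi = s$nlr_ci[2], ppv = s$ppv,
             ppv_lo = s$ppv_ci[1], ppv_hi = s$ppv_ci[2], npv = s$npv,
             npv_lo = s$npv_ci[1], npv_hi = s$npv_ci[2],
             accuracy_pct = s$accuracy_pct, youden = s$youden,
             stringsAsFactors = FALSE)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  for (line in x$log) cat(" ", line, "\n")
  cat("  conditions:", paste(names(x$diagnostics), collapse = ", "), "\n")
  invisible(x)
}

#' Write a report bundle as a directory of CSVs
#'
#' Numeric report cells are rounded only here (round half up: 1 decimal
#' for percentages and cutoffs, 2 for ratios, J and AUC); the full
#' precision bundle is additionally written as a JSON sidecar.
#'
#' @param bundle `report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, name) utils::write.csv(d, file.path(dir, name),
                                          row.names = FALSE, quote = FALSE)
  w(round_df(bundle$summary, 1), "summary.csv")
  w(round_df(bundle$reliability, 4), "reliability.csv")
  w(round_df(bundle$correlations, 3), "correlations.csv")
  w(round_df(bundle$correlations_by_age, 3), "correlations_by_age.csv")
  w(bundle$categories, "categories.csv")
  for (cname in names(bundle$diagnostics)) {
    d <- bundle$diagnostics[[cname]]
    for (col in grep("^(sn|sp|ppv|npv)", names(d), value = TRUE)) {
      d[[col]] <- round_half_up(100 * d[[col]], 1)
    }
    d$accuracy_pct <- round_half_up(d$accuracy_pct, 1)
    d$cutoff <- round_half_up(d$cutoff, 1)
    for (col in c("plr", "plr_lo", "plr_hi", "nlr", "nlr_lo", "nlr_hi",
                  "youden", "auc", "auc_lo", "auc_hi")) {
      d[[col]] <- round_half_up(d[[col]], 2)
    }
    w(d, paste0("diagnostics_", cname, ".csv"))
    for (lab in names(bundle$roc[[cname]])) {
      pts <- bundle$roc[[cname]][[lab]]$points
      w(round_df(pts, 4), sprintf("roc_%s_%s.csv", cname, lab))
    }
  }
  w(bundle$rejects, "rejects.csv")
  writeLines(bundle$log, file.path(dir, "run.log"))
  sidecar <- bundle[setdiff(names(bundle), "roc")]
  jsonlite::write_json(sidecar, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(dir)
}

round_df <- function(d, digits) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round_half_up, digits = digits)
  d
}

#' Command-line entry point
#'
#' Subcommands:
#' * `simulate --n N --seed S --out cohort.csv [--truth truth.csv]
#'    [--config cfg.yaml]` - write a synthetic cohort
#' * `analyze --cohort cohort.csv --lms lms.csv --out report_dir`
#'    - run the full analysis (`--lms synthetic` uses the bundled
#'    synthetic reference)
#' * `samplesize --sn 0.94 --sp 0.79 --prevalence 0.213
#'    [--precision 0.05] [--deff 1] [--nonresponse 0] [--out x.json]`
#'    - diagnostic-accuracy sample size, JSON output
#'
#' @param argv character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code: 0 success, 2 usage error, 1 runtime error.
#' @export
muac_cli <- function(argv) {
  usage <- function(msg) {
    message(msg)
    message("usage: muacscreen (simulate|analyze|samplesize) [options]")
    2L
  }
  if (length(argv) < 1) return(usage("no subcommand given"))
  cmd <- argv[1]
  opts <- parse_flags(argv[-1])
  if (is.character(opts)) return(usage(opts))
  res <- tryCatch({
    switch(cmd,
      simulate = cli_simulate(opts),
      analyze = cli_analyze(opts),
      samplesize = cli_samplesize(opts),
      return(usage(sprintf("unknown subcommand '%s'", cmd)))
    )
    0L
  }, muacscreen_error = function(e) {
    message(conditionMessage(e))
    if (inherits(e, "usage_error") || inherits(e, "file_error")) 2L else 1L
  }, error = function(e) { message(conditionMessage(e)); 1L })
  res
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(sprintf("unexpected argument '%s'", a))
    if (i + 1 > length(args)) return(sprintf("flag %s needs a value", a))
    opts[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

cli_simulate <- function(opts) {
  if (is.null(opts$out)) stop_muac("simulate requires --out", "usage_error")
  base <- if (!is.null(opts$config)) {
    cfg <- if (grepl("\\.ya?ml$", opts$config)) yaml::read_yaml(opts$config)
           else jsonlite::read_json(opts$config, simplifyVector = TRUE)
    do.call(cohort_config, cfg)
  } else cohort_config()
  if (!is.null(opts$n)) base$n <- as.integer(opts$n)
  if (!is.null(opts$seed)) base$seed <- as.integer(opts$seed)
  cohort <- generate_cohort(base)
  write_synthetic_cohort(cohort, opts$out, truth_path = opts$truth)
  message(sprintf("wrote %d records to %s", base$n, opts$out))
}

cli_analyze <- function(opts) {
  for (f in c("cohort", "out")) {
    if (is.null(opts[[f]])) {
      stop_muac(sprintf("analyze requires --%s", f), "usage_error")
    }
  }
  if (!file.exists(opts$cohort)) {
    stop_muac(sprintf("cohort file not found: %s", opts$cohort), "file_error")
  }
  lms <- opts$lms %||% "synthetic"
  lms_in <- if (identical(lms, "synthetic")) synthetic_lms() else {
    if (!file.exists(lms)) {
      stop_muac(sprintf("LMS file not found: %s", lms), "file_error")
    }
    lms
  }
  bundle <- run_analysis(opts$cohort, lms_in)
  write_report_bundle(bundle, opts$out)
  message(sprintf("report written to %s", opts$out))
}

cli_samplesize <- function(opts) {
  for (f in c("sn", "sp", "prevalence")) {
    if (is.null(opts[[f]])) {
      stop_muac(sprintf("samplesize requires --%s", f), "usage_error")
    }
  }
  res <- diag_sample_size(
    sensitivity = as.numeric(opts$sn), specificity = as.numeric(opts$sp),
    prevalence = as.numeric(opts$prevalence),
    precision = as.numeric(opts$precision %||% 0.05),
    alpha = as.numeric(opts$alpha %||% 0.05),
    design_effect = as.numeric(opts$deff %||% 1),
    nonresponse_rate = as.numeric(opts$nonresponse %||% 0))
  out <- jsonlite::toJSON(res[c("n_sens", "n_spec", "n_base", "n_final")],
                          auto_unbox = TRUE)
  if (!is.null(opts$out)) writeLines(out, opts$out) else cat(out, "\n")
}
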