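sleep_vars <- function() c("sol_min", "tst_min", "se_pct", "waso_min", "awakenings")

circadian_vars <- function() {
  c("day_mean", "day_sd", "night_mean", "night_sd", "m10", "midpoint_m10_h",
    "l5", "midpoint_l5_h", "ra", "iv", "is", "dichotomy_index")
}

hrv_vars <- function() {
  c("hr", "sdrr", "rmssd", "pnn50", "pnn20", "sd1", "sd2", "sd_ratio", "dc")
}

outcome_vars <- function() {
  c("admission_days", "any_readmission", "any_icu_readmission",
    "readmission_times", "readmission_days", "any_catheterization",
    "mean_readmission_days")
}

#' All actigraphy and HRV indicators for one subject
#'
#' Runs the single-subject pipeline: sleep scoring and nightly sleep
#' parameters, the nonparametric circadian indicator set (when the recording
#' is long enough), and the HRV indicator set when an RR series is supplied.
#'
#' @param epochs An epoch tibble (see [read_epochs()]).
#' @param rr Optional RR series (see [read_rr()]).
#' @param min_days Minimum recording length (days) for circadian analysis;
#'   shorter recordings yield NA circadian indicators.
#' @param ... Passed to [circadian_indicators()].
#' @return A one-row tibble combining sleep, circadian and HRV columns, plus
#'   `monitoring_days` and `circadian_eligible`.
#' @export
subject_indicators <- function(epochs, rr = NULL, min_days = 3, ...) {
  assert_epochs(epochs)
  scored <- score_sleep_wake(epochs)
  rest <- bed_intervals_from_epochs(epochs) %||% detect_major_rest(scored)
  slp <- sleep_summary(sleep_parameters(scored, rest))
  eligible <- eligible_for_circadian(epochs, min_days = min_days)
  circ <- if (eligible) {
    circadian_indicators(epochs, rest = rest, ...)
  } else {
    tibble::as_tibble(as.list(stats::setNames(
      rep(NA_real_, length(circadian_vars())), circadian_vars())))
  }
  es <- epoch_seconds(epochs)
  out <- dplyr::bind_cols(
    tibble::tibble(monitoring_days = sum(!missing_mask(epochs)) * es / 86400,
                   circadian_eligible = eligible),
    slp, circ)
  if (!is.null(rr)) out <- dplyr::bind_cols(out, hrv_indicators(rr))
  out
}

# Group means table + covariate-adjusted comparison for a set of variables.
group_comparison_rows <- function(cohort, vars, covariates,
                                  method = c("ancova", "ttest")) {
  method <- match.arg(method)
  mi <- cohort[cohort$group == "MI", , drop = FALSE]
  ctrl <- cohort[cohort$group == "control", , drop = FALSE]
  purrr::map_dfr(vars, function(v) {
    desc <- tibble::tibble(
      variable = v,
      mi_mean = mean(mi[[v]], na.rm = TRUE),
      mi_sd = sd(mi[[v]], na.rm = TRUE),
      ctrl_mean = mean(ctrl[[v]], na.rm = TRUE),
      ctrl_sd = sd(ctrl[[v]], na.rm = TRUE))
    res <- tryCatch({
      if (method == "ttest") {
        r <- ttest_independent(mi[[v]], ctrl[[v]], label = v)
        tibble::tibble(estimate = r$estimate, statistic = r$statistic,
                       df = r$df, p_value = r$p_value, sig_05 = r$sig_05,
                       sig_01 = r$sig_01, method = r$method)
      } else {
        td <- tidy(ancova(cohort, v, "group", covariates))
        tibble::tibble(estimate = td$estimate, statistic = td$statistic,
                       df = td$df, p_value = td$p_value, sig_05 = td$sig_05,
                       sig_01 = td$sig_01,
                       method = if (length(covariates) > 0)
                         sprintf("ANCOVA (%s)", paste(covariates, collapse = ","))
                       else "ANCOVA")
      }
    }, error = function(e) {
      tibble::tibble(estimate = NA_real_, statistic = NA_real_, df = NA_real_,
                     p_value = NA_real_, sig_05 = NA, sig_01 = NA,
                     method = sprintf("failed: %s", conditionMessage(e)))
    })
    dplyr::bind_cols(desc, res)
  })
}

# Correlation matrix rows (plain + partial) between vars and outcomes.
correlation_rows <- function(mi_rows, vars, outcomes,
                             adjust = c("age", "gender")) {
  purrr::map_dfr(vars, function(v) {
    purrr::map_dfr(outcomes, function(o) {
      un <- tryCatch(pearson_cor(mi_rows, v, o), error = function(e) NULL)
      ad <- tryCatch(partial_cor(mi_rows, v, o, covariates = adjust),
                     error = function(e) NULL)
      tibble::tibble(
        variable = v, outcome = o,
        r = if (is.null(un)) NA_real_ else un$r,
        p_value = if (is.null(un)) NA_real_ else un$p_value,
        n = if (is.null(un)) NA_integer_ else un$n,
        sig_05 = !is.null(un) && un$sig_05,
        sig_01 = !is.null(un) && un$sig_01,
        r_adjusted = if (is.null(ad)) NA_real_ else ad$r,
        p_adjusted = if (is.null(ad)) NA_real_ else ad$p_value,
        adj_sig_05 = !is.null(ad) && ad$sig_05,
        adj_sig_01 = !is.null(ad) && ad$sig_01)
    })
  })
}

#' Assemble the six study-style result tables
#'
#' Builds, from a per-subject cohort table, the standard report of an
#' actigraphy/HRV case-control and prognosis study:
#' \describe{
#'   \item{table1}{baseline characteristics: age and BMI by t test, gender
#'     by chi-square, laboratory variables by ANCOVA controlling for BMI;}
#'   \item{table2}{sleep parameters, ANCOVA controlling age, gender, BMI;}
#'   \item{table3}{circadian indicators, same adjustment;}
#'   \item{table4}{HRV indicators, same adjustment;}
#'   \item{table5}{correlations of sleep/circadian indicators with prognosis
#'     outcomes in the patient stratum, unadjusted and age/gender-adjusted;}
#'   \item{table6}{the same for HRV indicators.}
#' }
#' Significance is flagged at .05 and .01 without multiple-testing
#' correction (a Benjamini-Hochberg column can be added with
#' `p_adjust = TRUE`). Cells with missing values are dropped pairwise per
#' test.
#'
#' @param cohort A cohort tibble: one row per subject with `subject_id`,
#'   `group` (`"MI"`/`"control"`), `age`, `gender`, `bmi`, indicator columns
#'   and (patients only) outcome columns.
#' @param lab_vars Optional character vector of laboratory columns for
#'   table1.
#' @param out_dir If non-NULL, write `table1.csv` .. `table6.csv` there.
#' @param p_adjust Add Benjamini-Hochberg adjusted p values; default FALSE.
#' @return A named list of six tibbles, invisibly classed `cohort_report`.
#' @export
build_report <- function(cohort, lab_vars = character(), out_dir = NULL,
                         p_adjust = FALSE) {
  need <- c("subject_id", "group", "age", "gender", "bmi")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L) {
    abort(sprintf("cohort is missing required column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!any(cohort$group == "MI")) abort("cohort has an empty MI stratum")
  if (!any(cohort$group == "control")) abort("cohort has an empty control stratum")
  cohort$group <- factor(cohort$group, levels = c("control", "MI"))

  adj <- c("age", "gender", "bmi")
  t1 <- dplyr::bind_rows(
    group_comparison_rows(cohort, c("age", "bmi"), character(), method = "ttest"),
    tryCatch({
      g <- chisq_row(cohort, "gender", "group")
      tibble::tibble(variable = "gender",
                     mi_mean = mean(cohort$gender[cohort$group == "MI"] == "male"),
                     mi_sd = NA_real_,
                     ctrl_mean = mean(cohort$gender[cohort$group == "control"] == "male"),
                     ctrl_sd = NA_real_, estimate = NA_real_,
                     statistic = g$statistic, df = g$df, p_value = g$p_value,
                     sig_05 = g$sig_05, sig_01 = g$sig_01, method = g$method)
    }, error = function(e) NULL),
    if (length(lab_vars) > 0)
      group_comparison_rows(cohort, lab_vars, "bmi", method = "ancova"))

  present <- function(vars) intersect(vars, names(cohort))
  t2 <- group_comparison_rows(cohort, present(sleep_vars()), adj)
  t3 <- group_comparison_rows(cohort, present(circadian_vars()), adj)
  t4 <- group_comparison_rows(cohort, present(hrv_vars()), adj)

  mi_rows <- cohort[cohort$group == "MI", , drop = FALSE]
  mi_rows$gender_num <- as.numeric(mi_rows$gender == "male")
  out_cols <- present(outcome_vars())
  acti_vars <- present(c(sleep_vars(), circadian_vars()))
  t5 <- correlation_rows(mi_rows, acti_vars, out_cols,
                         adjust = c("age", "gender_num"))
  t6 <- correlation_rows(mi_rows, present(hrv_vars()), out_cols,
                         adjust = c("age", "gender_num"))

  tables <- list(table1 = t1, table2 = t2, table3 = t3,
                 table4 = t4, table5 = t5, table6 = t6)
  if (p_adjust) {
    tables <- purrr::map(tables, function(tb) {
      if ("p_value" %in% names(tb)) {
        tb$p_bh <- stats::p.adjust(tb$p_value, method = "BH")
      }
      tb
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(tables, function(tb, nm) {
      readr::write_csv(tb, file.path(out_dir, paste0(nm, ".csv")))
    })
  }
  invisible(structure(tables, class = c("cohort_report", "list")))
}

#' Per-subject indicator table for a simulated cohort, in memory
#'
#' Runs [subject_indicators()] on every subject of a [simulate_cohort()]
#' result and joins the metadata/outcome table, without touching disk.
#' Equivalent to [write_cohort()] followed by [analyze_cohort()] up to CSV
#' round-tripping.
#'
#' @param sim A `cohort_sim`.
#' @param min_days Circadian eligibility threshold in days.
#' @return A cohort tibble ready for [build_report()].
#' @export
cohort_indicator_table <- function(sim, min_days = 3) {
  stopifnot(inherits(sim, "cohort_sim"))
  ind <- purrr::map2_dfr(sim$subjects$subject_id, seq_len(nrow(sim$subjects)),
                         function(id, i) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = id),
      suppressWarnings(subject_indicators(sim$subjects$activity[[i]],
                                          rr = sim$subjects$rr[[i]],
                                          min_days = min_days)))
  })
  dplyr::left_join(sim$cohort, ind, by = "subject_id")
}

#' Run the full pipeline on a cohort manifest
#'
#' Reads a manifest (JSON listing per-subject activity and RR files plus the
#' cohort metadata/outcome CSV, as written by [write_cohort()]), computes
#' every subject's sleep, circadian and HRV indicators, joins them with the
#' metadata and outcomes, and assembles the six report tables. Subjects with
#' recordings shorter than `min_days` days get NA circadian indicators, so
#' they drop out of the circadian rows pairwise, mirroring the
#' recording-length exclusion rule.
#'
#' @param manifest_path Path to `manifest.json`.
#' @param out_dir If non-NULL, write the table CSVs and a `run_log.json`
#'   there (deterministic content for a given input and seed).
#' @param min_days Circadian eligibility threshold in days; default 3.
#' @param lab_vars Laboratory columns for table1, if present in the cohort
#'   CSV.
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return A list with `cohort` (the per-subject indicator table) and
#'   `tables` (the [build_report()] list).
#' @export
analyze_cohort <- function(manifest_path, out_dir = NULL, min_days = 3,
                           lab_vars = character(), seed = NULL) {
  manifest <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  if (is.null(manifest$subjects) || length(manifest$subjects) == 0L) {
    abort("manifest lists no subjects")
  }
  meta <- readr::read_csv(file.path(base, manifest$cohort_file),
                          show_col_types = FALSE, progress = FALSE)
  ind <- purrr::map_dfr(manifest$subjects, function(s) {
    epochs <- read_epochs(file.path(base, s$activity_file),
                          subject_id = s$subject_id)
    rr <- if (!is.null(s$rr_file)) read_rr(file.path(base, s$rr_file)) else NULL
    dplyr::bind_cols(tibble::tibble(subject_id = s$subject_id),
                     suppressWarnings(
                       subject_indicators(epochs, rr = rr, min_days = min_days)))
  })
  cohort <- dplyr::left_join(meta, ind, by = "subject_id")
  tables <- build_report(cohort, lab_vars = lab_vars, out_dir = out_dir)
  if (!is.null(out_dir)) {
    readr::write_csv(cohort, file.path(out_dir, "cohort_indicators.csv"))
    log <- list(
      package = "actirhythm",
      version = as.character(utils::packageVersion("actirhythm")),
      manifest = basename(manifest_path),
      n_subjects = length(manifest$subjects),
      min_days = min_days,
      seed = seed,
      config_hash = rlang::hash(list(min_days = min_days, lab_vars = lab_vars))
    )
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(cohort = cohort, tables = tables)
}
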