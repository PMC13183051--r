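#' Validate a cohort table
#'
#' Schema check for the cohort CSV dictionary: required columns present,
#' GOS levels in I-V, FAA numeric, non-negative marker values not enforced
#' (markers may legitimately be missing).
#'
#' @param records Data frame (or path to a CSV, which is read first).
#' @return Character vector of issues; empty when the table is well formed.
#' @examples
#' validate_cohort(generate_cohort(cohort_config(n_good = 5, n_poor = 3)))
#' @export
validate_cohort <- function(records) {
  if (is.character(records)) {
    if (!file.exists(records)) return(sprintf("file not found: %s", records))
    records <- read.csv(records, stringsAsFactors = FALSE)
  }
  issues <- character()
  required <- c("faa_e3", "gos_level")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    issues <- c(issues, sprintf("missing required column(s): %s",
                                paste(missing_cols, collapse = ", ")))
  }
  if ("gos_level" %in% names(records)) {
    lev <- records$gos_level
    if (is.character(lev) || is.factor(lev)) {
      lev <- match(toupper(as.character(lev)), c("I", "II", "III", "IV", "V"))
    }
    bad <- which(is.na(lev) | lev != round(lev) | lev < 1 | lev > 5)
    for (i in bad) {
      issues <- c(issues, sprintf(
        "row %d: field `gos_level` value '%s' outside levels I-V", i,
        records$gos_level[i]))
    }
  }
  if ("faa_e3" %in% names(records)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(records$faa_e3))))
    for (i in bad) {
      issues <- c(issues, sprintf("row %d: field `faa_e3` is not numeric", i))
    }
  }
  issues
}

#' Validate an EEG channel-matrix file
#'
#' Checks that the CSV + sidecar pair is readable, that the sampling rate is
#' positive, and that the frontal channels F3 and F4 needed for the FAA
#' index are present.
#'
#' @param path Path to an EEG CSV written by [write_eeg_csv()].
#' @return Character vector of issues; empty when well formed.
#' @export
validate_eeg_file <- function(path) {
  if (!file.exists(path)) return(sprintf("file not found: %s", path))
  issues <- character()
  header <- names(read.csv(path, nrows = 1, check.names = FALSE))
  for (ch in c("F3", "F4")) {
    if (!toupper(ch) %in% toupper(header)) {
      issues <- c(issues, sprintf("missing channel column `%s`", ch))
    }
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    issues <- c(issues, sprintf("missing sampling-rate sidecar `%s`", sidecar))
  } else {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs) || !is.numeric(meta$fs) || meta$fs <= 0) {
      issues <- c(issues, "field `fs` in sidecar must be a positive number")
    }
  }
  issues
}

#' Full statistical analysis of a cohort
#'
#' Runs the cohort-level battery on a patient table: univariate two-group
#' comparisons (pooled t for continuous variables, chi-square — with a
#' Fisher fallback when an expected count is zero — for categorical ones),
#' the binary logistic model in FAA, SE duration and time-to-cessation (the
#' published coding: binary covariates 0/1, FAA at its original reported
#' value, poor prognosis = 1), the empirical ROC of FAA with its
#' Youden-optimal cutoff, and the cutoff-stratified outcome and marker
#' tables.
#'
#' @param records Cohort data frame (see [generate_cohort()] for the column
#'   dictionary). Rows with missing values are dropped listwise per test.
#' @param cutoff Optional fixed FAA cutoff for stratification; default is
#'   the Youden-optimal cutoff estimated from the data.
#' @return List with `univariate` (data frame), `logistic`
#'   (`logistic_fit`), `roc` (`roc_curve`), `youden` (`cutoff_result`),
#'   `stratified` (from [stratify_by_cutoff()]), `n_good`, `n_poor`.
#' @examples
#' res <- analyze_cohort(generate_cohort(cohort_config(seed = 7)))
#' res$roc$auc
#' @export
analyze_cohort <- function(records, cutoff = NULL) {
  records <- as.data.frame(records)
  if (!"prognosis" %in% names(records)) {
    records$prognosis <- as.character(dichotomize_gos(records$gos_level))
  }
  prog <- factor(records$prognosis, levels = c("good", "poor"))
  if (nlevels(droplevels(prog)) < 2) {
    stop("both prognosis groups must be present for a cohort analysis",
         call. = FALSE)
  }

  uni <- list()
  add_uni <- function(variable, method, statistic, df, p) {
    uni[[length(uni) + 1L]] <<- data.frame(
      variable = variable, method = method, statistic = statistic,
      df = df, p = p, stringsAsFactors = FALSE)
  }
  for (v in c("age_yr", "bmi", "picu_days", "faa_e3")) {
    if (!v %in% names(records)) next
    keep <- !is.na(records[[v]])
    tt <- pooled_t_test(x = records[[v]][keep & prog == "good"],
                        y = records[[v]][keep & prog == "poor"])
    add_uni(v, "t_pooled", tt$statistic, tt$df, tt$p.value)
  }
  for (v in c("sex", "se_duration_gt60", "epilepsy_history", "seizure_type",
              "time_to_cessation_gt30", "underlying_disease",
              "respiratory_failure", "vasopressor_use")) {
    if (!v %in% names(records)) next
    keep <- !is.na(records[[v]])
    tab <- table(records[[v]][keep], prog[keep])
    if (any(dim(tab) < 2)) next
    res <- tryCatch(chi_square_test(unclass(tab)), error = function(e) NULL)
    if (is.null(res)) {
      if (all(dim(tab) == 2)) {
        res <- fisher_exact_test(unclass(tab))
      } else {
        next
      }
    }
    add_uni(v, res$method, res$statistic, res$df, res$p.value)
  }
  univariate <- do.call(rbind, uni)

  design <- cbind(
    faa_e3 = records$faa_e3,
    se_duration_gt60 = as.numeric(records$se_duration_gt60 == "yes"),
    time_to_cessation_gt30 = as.numeric(records$time_to_cessation_gt30 == "yes"))
  keep <- stats::complete.cases(design)
  fit <- fit_logistic(design[keep, , drop = FALSE],
                      as.integer(prog[keep] == "poor"))

  roc <- empirical_roc(records$faa_e3, prog, positive = "poor",
                       orientation = "lower_score_positive")
  yj <- youden_optimal(roc)
  cut_use <- cutoff %||% yj$cutoff
  strat <- stratify_by_cutoff(records, cut_use)

  list(univariate = univariate, logistic = fit, roc = roc, youden = yj,
       stratified = strat,
       n_good = sum(prog == "good"), n_poor = sum(prog == "poor"))
}

#' Run configuration for the pipeline
#'
#' @param mode One of `"synth_end_to_end"`, `"cohort_only"`, `"eeg_only"`,
#'   `"worked_examples"`.
#' @param input Input path (cohort CSV for `cohort_only`, EEG CSV for
#'   `eeg_only`); unused by the synthetic and worked-examples modes.
#' @param out_dir Output directory for the JSON report and CSV sidecars.
#' @param seed Integer seed, recorded in every report.
#' @param cohort Optional [cohort_config()] override for synthetic modes.
#' @param eeg Optional [eeg_synthesis_spec()] override.
#' @param eeg_params Named list of [faa_from_recording()] arguments.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synth_end_to_end", "cohort_only", "eeg_only",
                                "worked_examples"),
                       input = NULL, out_dir = tempfile("faaprog_run_"),
                       seed = 1, cohort = NULL, eeg = NULL,
                       eeg_params = list()) {
  mode <- match.arg(mode)
  if (mode %in% c("cohort_only", "eeg_only")) {
    if (is.null(input) || !file.exists(input)) {
      stop_invalid("input", sprintf("mode '%s' requires an existing input file",
                                    mode))
    }
  }
  structure(list(mode = mode, input = input, out_dir = out_dir, seed = seed,
                 cohort = cohort, eeg = eeg, eeg_params = eeg_params),
            class = "run_config")
}

report_cohort_results <- function(res) {
  list(
    n_good = res$n_good, n_poor = res$n_poor,
    univariate = res$univariate,
    logistic = res$logistic$coefficients,
    roc = list(auc = res$roc$auc, se = res$roc$se,
               ci_lower = res$roc$ci[1], ci_upper = res$roc$ci[2],
               orientation = res$roc$orientation,
               positive_class = res$roc$positive_class),
    youden = list(cutoff = res$youden$cutoff, youden_j = res$youden$youden_j,
                  sensitivity = res$youden$sensitivity,
                  specificity = res$youden$specificity),
    stratified = list(
      cutoff = res$stratified$cutoff,
      n_le = res$stratified$n_le, n_gt = res$stratified$n_gt,
      outcome_counts = as.data.frame(res$stratified$outcome_table),
      outcome_chisq = res$stratified$outcome_test$statistic,
      outcome_p = res$stratified$outcome_test$p.value,
      marker_tests = res$stratified$marker_tests)
  )
}

#' Run the pipeline
#'
#' Executes the selected mode and writes a single JSON report (plus CSV
#' sidecars for the ROC coordinates and, in synthetic modes, the generated
#' cohort) into `config$out_dir`. Every report records the mode, seed and
#' effective parameters, and runs are byte-identical under a fixed seed.
#'
#' Modes:
#' * `worked_examples` — recompute every reproducible published statistic
#'   from the embedded summary tables ([worked_examples()]).
#' * `synth_end_to_end` — generate a synthetic cohort plus one synthetic
#'   EEG subject per prognosis group, push the EEG through the signal
#'   chain, and run the full cohort analysis.
#' * `cohort_only` — analyze an existing cohort CSV.
#' * `eeg_only` — compute the FAA index of an existing EEG CSV.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (a list; also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(mode = config$mode, seed = config$seed,
                 package_version = as.character(utils::packageVersion("faaprog")))

  if (config$mode == "worked_examples") {
    we <- worked_examples()
    report$worked_examples <- we
    report$all_pass <- all(we$pass, na.rm = TRUE)
    write.csv(we, file.path(config$out_dir, "worked_examples.csv"),
              row.names = FALSE)
  } else if (config$mode == "cohort_only") {
    records <- read_cohort_csv(config$input)
    res <- analyze_cohort(records)
    report$cohort <- report_cohort_results(res)
    write.csv(res$roc$points, file.path(config$out_dir, "roc_points.csv"),
              row.names = FALSE)
  } else if (config$mode == "eeg_only") {
    issues <- validate_eeg_file(config$input)
    if (length(issues)) {
      stop(paste0("stage eeg_only, input validation failed:\n  ",
                  paste(issues, collapse = "\n  ")), call. = FALSE)
    }
    rec <- read_eeg_csv(config$input)
    report$faa <- do.call(faa_from_recording, c(list(rec), config$eeg_params))
  } else { # synth_end_to_end
    cc <- config$cohort %||% cohort_config(seed = config$seed)
    records <- generate_cohort(cc)
    write_cohort_csv(records, file.path(config$out_dir, "cohort.csv"))
    res <- analyze_cohort(records)
    report$cohort <- report_cohort_results(res)
    write.csv(res$roc$points, file.path(config$out_dir, "roc_points.csv"),
              row.names = FALSE)
    specs <- list(
      good = config$eeg %||% eeg_synthesis_spec(
        target_faa = cc$faa_mean_good / 1000, seed = config$seed),
      poor = eeg_synthesis_spec(target_faa = cc$faa_mean_poor / 1000,
                                seed = config$seed + 1))
    report$eeg_subjects <- lapply(specs, function(sp) {
      rec <- generate_eeg(sp)
      out <- do.call(faa_from_recording, c(list(rec), config$eeg_params))
      out$target_faa_reported <- 1000 * sp$target_faa
      out
    })
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(report)
}
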