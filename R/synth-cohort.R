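#' Default covariate marginals for the synthetic cohort
#'
#' Stratum-conditional category probabilities for every categorical
#' covariate and stratum-conditional moments for the continuous covariates,
#' taken from the published cohort's univariate table
#' ([ref_cohort_tables()]). Probabilities are the published counts divided
#' by the stratum sizes (126 good / 51 poor).
#'
#' @return Named list: each categorical entry has `levels`, `p_good`,
#'   `p_poor`; `continuous` holds per-variable mean/SD by stratum.
#' @export
default_covariate_marginals <- function() {
  ref <- ref_cohort_tables()
  out <- lapply(ref$categorical, function(ct) {
    list(levels = rownames(ct$counts),
         p_good = ct$counts[, "good"] / sum(ct$counts[, "good"]),
         p_poor = ct$counts[, "poor"] / sum(ct$counts[, "poor"]))
  })
  cont <- ref$continuous
  out$continuous <- cont[cont$variable != "faa_e3", ]
  out
}

#' Default serum-marker moments for the synthetic cohort
#'
#' Mean/SD of GFAP (ng/L), S100-beta (ug/L) and GABA (umol/L), before and
#' after treatment, conditional on the FAA stratum (at or below vs above the
#' published 88.96 cutoff on the x 10^-3 scale), from
#' [ref_cohort_tables()].
#'
#' @return List with `table` (data frame of moments) and `cutoff` (the FAA
#'   value separating the marker strata).
#' @export
default_marker_moments <- function() {
  list(table = ref_cohort_tables()$markers, cutoff = 88.96)
}

#' Configuration for a synthetic patient cohort
#'
#' Defaults reproduce the statistical structure of the published cohort:
#' 126 good- / 51 poor-prognosis patients, stratum-conditional FAA normals
#' (89.10 +/- 17.04 vs 66.64 +/- 17.77 on the x 10^-3 scale), published
#' covariate marginals and serum-marker moments, and a logistic outcome
#' model in FAA and time-to-seizure-cessation with slopes -0.077 (per FAA
#' reported unit) and 1.010 (category > 30 min). The outcome intercept is
#' calibrated numerically so the marginal poor-prognosis rate matches
#' `n_poor / (n_good + n_poor)` (51/177 at the defaults); pass
#' `outcome_model = list(intercept = ...)` to override.
#'
#' @param n_good,n_poor Stratum sizes (non-negative integers).
#' @param faa_mean_good,faa_sd_good,faa_mean_poor,faa_sd_poor FAA stratum
#'   moments on the reported (x 10^-3) scale; SDs must be positive.
#' @param covariate_marginals As [default_covariate_marginals()].
#' @param marker_moments As [default_marker_moments()].
#' @param outcome_model List with `intercept` (NULL = calibrate),
#'   `beta_faa`, `beta_time`.
#' @param gos_poor_probs Probabilities of GOS levels I-IV within the poor
#'   stratum (sums to 1).
#' @param seed Integer seed; identical config + seed gives an identical
#'   cohort.
#' @return An object of class `cohort_config` (validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_good = 126, n_poor = 51,
                          faa_mean_good = 89.10, faa_sd_good = 17.04,
                          faa_mean_poor = 66.64, faa_sd_poor = 17.77,
                          covariate_marginals = default_covariate_marginals(),
                          marker_moments = default_marker_moments(),
                          outcome_model = list(intercept = NULL,
                                               beta_faa = -0.077,
                                               beta_time = 1.010),
                          gos_poor_probs = c(0.10, 0.20, 0.35, 0.35),
                          seed = 1) {
  if (!(n_good >= 0 && n_poor >= 0 && n_good == round(n_good) &&
        n_poor == round(n_poor))) {
    stop_invalid("n_good/n_poor", "stratum sizes must be non-negative integers")
  }
  if (n_good + n_poor == 0) stop_invalid("n_good/n_poor", "cohort is empty")
  for (f in c("faa_sd_good", "faa_sd_poor")) {
    if (!(get(f) > 0)) stop_invalid(f, "must be positive")
  }
  for (nm in setdiff(names(covariate_marginals), "continuous")) {
    cm <- covariate_marginals[[nm]]
    for (p in c("p_good", "p_poor")) {
      if (any(cm[[p]] < 0) || abs(sum(cm[[p]]) - 1) > 1e-12) {
        stop_invalid(sprintf("covariate_marginals$%s$%s", nm, p),
                     "category probabilities must be non-negative and sum to 1 (within 1e-12)")
      }
      if (length(cm[[p]]) != length(cm$levels)) {
        stop_invalid(sprintf("covariate_marginals$%s$%s", nm, p),
                     "one probability per level required")
      }
    }
  }
  if (any(marker_moments$table$sd_low <= 0) ||
      any(marker_moments$table$sd_high <= 0)) {
    stop_invalid("marker_moments", "all marker SDs must be positive")
  }
  if (abs(sum(gos_poor_probs) - 1) > 1e-12 || length(gos_poor_probs) != 4 ||
      any(gos_poor_probs < 0)) {
    stop_invalid("gos_poor_probs", "need 4 non-negative probabilities summing to 1")
  }
  om <- modifyList(list(intercept = NULL, beta_faa = -0.077, beta_time = 1.010),
                   outcome_model %||% list())
  structure(
    list(n_good = n_good, n_poor = n_poor,
         faa_mean_good = faa_mean_good, faa_sd_good = faa_sd_good,
         faa_mean_poor = faa_mean_poor, faa_sd_poor = faa_sd_poor,
         covariate_marginals = covariate_marginals,
         marker_moments = marker_moments, outcome_model = om,
         gos_poor_probs = gos_poor_probs, seed = seed),
    class = "cohort_config")
}

#' Calibrate the outcome-model intercept to a target event rate
#'
#' Solves, by numerical integration over the two-component FAA normal
#' mixture and the binary time-to-cessation covariate, for the intercept
#' `b0` such that the marginal poor-prognosis probability
#' `E[plogis(b0 + beta_faa * FAA + beta_time * T)]` equals `target_rate`.
#' Deterministic (no simulation).
#'
#' @param config A [cohort_config()].
#' @param target_rate Desired marginal event rate; defaults to
#'   `n_poor / (n_good + n_poor)`.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_outcome_intercept <- function(config,
                                        target_rate = config$n_poor /
                                          (config$n_good + config$n_poor)) {
  stopifnot(inherits(config, "cohort_config"))
  w_good <- config$n_good / (config$n_good + config$n_poor)
  tm <- config$covariate_marginals$time_to_cessation_gt30
  p_time <- w_good * tm$p_good[tm$levels == "yes"] +
    (1 - w_good) * tm$p_poor[tm$levels == "yes"]
  bf <- config$outcome_model$beta_faa
  bt <- config$outcome_model$beta_time
  marginal_rate <- function(b0) {
    comp <- function(mu, sigma, shift) {
      integrate(function(z) plogis(b0 + shift + bf * (mu + sigma * z)) *
                  stats::dnorm(z), -8, 8)$value
    }
    mix <- function(shift) {
      w_good * comp(config$faa_mean_good, config$faa_sd_good, shift) +
        (1 - w_good) * comp(config$faa_mean_poor, config$faa_sd_poor, shift)
    }
    (1 - p_time) * mix(0) + p_time * mix(bt)
  }
  uniroot(function(b0) marginal_rate(b0) - target_rate,
          lower = -30, upper = 30, tol = 1e-10)$root
}

draw_categoricals <- function(marginals, stratum) {
  n <- length(stratum)
  out <- list()
  for (nm in setdiff(names(marginals), "continuous")) {
    cm <- marginals[[nm]]
    v <- character(n)
    for (s in c("good", "poor")) {
      idx <- stratum == s
      if (!any(idx)) next
      v[idx] <- sample(cm$levels, sum(idx), replace = TRUE,
                       prob = cm[[paste0("p_", s)]])
    }
    out[[nm]] <- v
  }
  out
}

draw_continuous <- function(marginals, stratum) {
  cont <- marginals$continuous
  n <- length(stratum)
  out <- list()
  for (i in seq_len(nrow(cont))) {
    v <- numeric(n)
    g <- stratum == "good"
    v[g] <- rnorm(sum(g), cont$mean_good[i], cont$sd_good[i])
    v[!g] <- rnorm(sum(!g), cont$mean_poor[i], cont$sd_poor[i])
    out[[cont$variable[i]]] <- v
  }
  out
}

draw_markers <- function(marker_moments, faa) {
  tab <- marker_moments$table
  low <- faa <= marker_moments$cutoff
  out <- list()
  for (i in seq_len(nrow(tab))) {
    v <- numeric(length(faa))
    v[low] <- rnorm(sum(low), tab$mean_low[i], tab$sd_low[i])
    v[!low] <- rnorm(sum(!low), tab$mean_high[i], tab$sd_high[i])
    out[[paste(tab$marker[i], tab$timepoint[i], sep = "_")]] <- v
  }
  out
}

#' Generate a synthetic patient cohort
#'
#' Two generation modes:
#'
#' * `"moment_matching"` (default): the prognosis label is fixed by stratum
#'   (`n_good` good + `n_poor` poor records); FAA, continuous covariates and
#'   categorical covariates are drawn from the stratum-conditional
#'   distributions, so group summaries converge to the configured moments.
#' * `"model"`: FAA is drawn from the two-component mixture, covariates
#'   from the pooled marginals, and the prognosis is drawn from the
#'   logistic outcome model in FAA and time-to-cessation — the mode used
#'   for parameter-recovery experiments.
#'
#' Serum markers are always drawn conditional on the record's FAA stratum
#' relative to the marker cutoff. GOS level is V for good prognosis and
#' drawn from `gos_poor_probs` over I-IV for poor.
#'
#' @param config A [cohort_config()].
#' @param mode `"moment_matching"` or `"model"`.
#' @return A data frame, one row per patient, with columns `patient_id`,
#'   `age_yr`, `sex`, `bmi`, `se_duration_gt60`, `epilepsy_history`,
#'   `seizure_type`, `time_to_cessation_gt30`, `picu_days`, `faa_e3`,
#'   `underlying_disease`, `respiratory_failure`, `vasopressor_use`,
#'   `gfap_pre`, `gfap_post`, `s100b_pre`, `s100b_post`, `gaba_pre`,
#'   `gaba_post`, `gos_level` (integer 1-5), `prognosis`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' table(cohort$prognosis)
#' @export
generate_cohort <- function(config = cohort_config(),
                            mode = c("moment_matching", "model")) {
  stopifnot(inherits(config, "cohort_config"))
  mode <- match.arg(mode)
  n <- config$n_good + config$n_poor
  withr::with_seed(config$seed, {
    if (mode == "moment_matching") {
      stratum <- rep(c("good", "poor"), c(config$n_good, config$n_poor))
      faa <- numeric(n)
      g <- stratum == "good"
      faa[g] <- rnorm(sum(g), config$faa_mean_good, config$faa_sd_good)
      faa[!g] <- rnorm(sum(!g), config$faa_mean_poor, config$faa_sd_poor)
      cats <- draw_categoricals(config$covariate_marginals, stratum)
      conts <- draw_continuous(config$covariate_marginals, stratum)
      prognosis <- stratum
    } else {
      om <- config$outcome_model
      b0 <- om$intercept %||% calibrate_outcome_intercept(config)
      w_good <- config$n_good / n
      comp_good <- runif(n) < w_good
      faa <- ifelse(comp_good,
                    rnorm(n, config$faa_mean_good, config$faa_sd_good),
                    rnorm(n, config$faa_mean_poor, config$faa_sd_poor))
      # pooled marginals: covariates drawn without reference to the outcome
      pooled <- lapply(config$covariate_marginals, function(cm) {
        if (is.data.frame(cm)) return(cm)
        list(levels = cm$levels,
             p_good = w_good * cm$p_good + (1 - w_good) * cm$p_poor,
             p_poor = w_good * cm$p_good + (1 - w_good) * cm$p_poor)
      })
      stratum <- rep("good", n)  # placeholder; draws use pooled probabilities
      cats <- draw_categoricals(pooled, stratum)
      conts <- draw_continuous(config$covariate_marginals,
                               sample(c("good", "poor"), n, replace = TRUE,
                                      prob = c(w_good, 1 - w_good)))
      time01 <- as.numeric(cats$time_to_cessation_gt30 == "yes")
      eta <- b0 + om$beta_faa * faa + om$beta_time * time01
      prognosis <- ifelse(rbinom(n, 1, plogis(eta)) == 1, "poor", "good")
    }

    gos <- integer(n)
    gos[prognosis == "good"] <- 5L
    n_poor_rec <- sum(prognosis == "poor")
    if (n_poor_rec > 0) {
      gos[prognosis == "poor"] <- sample(1:4, n_poor_rec, replace = TRUE,
                                         prob = config$gos_poor_probs)
    }
    markers <- draw_markers(config$marker_moments, faa)

    df <- data.frame(patient_id = seq_len(n),
                     age_yr = conts$age_yr, sex = cats$sex, bmi = conts$bmi,
                     se_duration_gt60 = cats$se_duration_gt60,
                     epilepsy_history = cats$epilepsy_history,
                     seizure_type = cats$seizure_type,
                     time_to_cessation_gt30 = cats$time_to_cessation_gt30,
                     picu_days = conts$picu_days, faa_e3 = faa,
                     underlying_disease = cats$underlying_disease,
                     respiratory_failure = cats$respiratory_failure,
                     vasopressor_use = cats$vasopressor_use,
                     stringsAsFactors = FALSE)
    for (nm in names(markers)) df[[nm]] <- markers[[nm]]
    df$gos_level <- gos
    df$prognosis <- as.character(dichotomize_gos(gos))
    df
  })
}

#' Read / write the cohort CSV format
#'
#' Plain CSV with the column dictionary documented in
#' [generate_cohort()]. `read_cohort_csv` validates the result with
#' [validate_cohort()] and fails on structural issues.
#'
#' @param records Cohort data frame.
#' @param path CSV path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the validated data frame.
#' @export
write_cohort_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  issues <- validate_cohort(df)
  if (length(issues)) {
    stop(paste0("invalid cohort file:\n  ", paste(issues, collapse = "\n  ")),
         call. = FALSE)
  }
  if (!"prognosis" %in% names(df)) {
    df$prognosis <- as.character(dichotomize_gos(df$gos_level))
  }
  df
}
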