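#' Empirical ROC curve with trapezoidal AUC
#'
#' Builds the empirical ROC of a continuous score against a binary outcome.
#' Candidate thresholds are the distinct observed scores. With the default
#' orientation `lower_score_positive` a subject tests positive when
#' `score <= threshold` — the convention for a marker whose *low* values
#' predict the event (low frontal alpha asymmetry predicting poor
#' prognosis). AUC is computed by the trapezoidal rule, which on the full
#' threshold set equals the Mann-Whitney statistic
#' `U / (n_pos * n_neg)` with half-weight for ties. The Hanley-McNeil
#' standard error and 95% CI are attached.
#'
#' @param scores Numeric marker values (no NAs).
#' @param labels Outcome per subject; coerced to factor. Both classes must
#'   be present.
#' @param positive Label of the positive (event) class, default `"poor"`.
#' @param orientation `"lower_score_positive"` (default) or
#'   `"higher_score_positive"`.
#' @return An object of class `roc_curve`: list with `points` (data frame:
#'   `threshold`, `tp`, `fp`, `fn`, `tn`, `tpr`, `fpr`), `auc`, `se`, `ci`,
#'   `n_pos`, `n_neg`, `positive_class`, `orientation`.
#' @examples
#' roc <- empirical_roc(c(1, 2, 3, 4, 5, 6), rep(c("poor", "good"), each = 3))
#' roc$auc
#' @export
empirical_roc <- function(scores, labels,
                          positive = "poor",
                          orientation = c("lower_score_positive",
                                          "higher_score_positive")) {
  orientation <- match.arg(orientation)
  scores <- as.numeric(scores)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA",
                                           call. = FALSE)
  labels <- as.factor(labels)
  if (!positive %in% levels(labels)) {
    stop(sprintf("positive class '%s' not found in labels", positive),
         call. = FALSE)
  }
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both outcome classes must be present to build a ROC curve",
         call. = FALSE)
  }

  thr <- sort(unique(scores))
  if (orientation == "lower_score_positive") {
    tp <- vapply(thr, function(t) sum(is_pos & scores <= t), numeric(1))
    fp <- vapply(thr, function(t) sum(!is_pos & scores <= t), numeric(1))
  } else {
    thr <- rev(thr)
    tp <- vapply(thr, function(t) sum(is_pos & scores >= t), numeric(1))
    fp <- vapply(thr, function(t) sum(!is_pos & scores >= t), numeric(1))
  }
  pts <- data.frame(threshold = c(if (orientation == "lower_score_positive")
    -Inf else Inf, thr),
    tp = c(0, tp), fp = c(0, fp))
  pts$fn <- n_pos - pts$tp
  pts$tn <- n_neg - pts$fp
  pts$tpr <- pts$tp / n_pos
  pts$fpr <- pts$fp / n_neg

  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  hm <- hanley_mcneil_se(auc, n_pos, n_neg)
  structure(list(points = pts, auc = auc, se = hm$se, ci = hm$ci,
                 n_pos = n_pos, n_neg = n_neg, positive_class = positive,
                 orientation = orientation),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> AUC = %.4f (SE %.4f, 95%% CI %.4f-%.4f), %d pos / %d neg, %s\n",
    x$auc, x$se, x$ci[1], x$ci[2], x$n_pos, x$n_neg, x$orientation))
  invisible(x)
}

#' Hanley-McNeil standard error of an empirical AUC
#'
#' Distribution-free approximation: with `A` the AUC,
#' `Q1 = A / (2 - A)`, `Q2 = 2 A^2 / (1 + A)`, and
#' `SE^2 = [A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)] /
#' (n_pos * n_neg)`. The 95% CI is `A +/- 1.96 SE`, clipped to \[0, 1\].
#'
#' @param auc AUC in \[0, 1\].
#' @param n_pos,n_neg Positive / negative class sizes (each >= 2).
#' @return List with `se` and `ci` (length-2 vector). A degenerate AUC of
#'   exactly 0 or 1 returns `se = 0` with a warning.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  if (!(auc >= 0 && auc <= 1)) stop_invalid("auc", "must lie in [0, 1]")
  if (n_pos < 2 || n_neg < 2) stop("need n_pos >= 2 and n_neg >= 2", call. = FALSE)
  if (auc == 0 || auc == 1) {
    warning("degenerate AUC of 0 or 1: standard error set to 0")
    return(list(se = 0, ci = c(auc, auc)))
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  se <- sqrt(v)
  ci <- pmin(1, pmax(0, auc + c(-1.96, 1.96) * se))
  list(se = se, ci = ci)
}

confusion_metrics <- function(tp, fn, fp, tn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       youden_j = sens + spec - 1,
       confusion = matrix(c(tp, fp, fn, tn), nrow = 2,
                          dimnames = list(truth = c("positive", "negative"),
                                          call = c("positive", "negative"))))
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Selects the threshold maximizing the Youden index
#' `J = sensitivity + specificity - 1` over all finite thresholds of the
#' curve. Ties are broken by maximal sensitivity, then by the lower cutoff.
#'
#' @param roc A `roc_curve` from [empirical_roc()].
#' @return An object of class `cutoff_result`: list with `cutoff`,
#'   `youden_j`, `sensitivity`, `specificity`, and the 2 x 2 `confusion`
#'   matrix (truth x test call) at the optimum.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  sens <- pts$tpr
  spec <- 1 - pts$fpr
  j <- sens + spec - 1
  ord <- order(-j, -sens, pts$threshold)
  best <- pts[ord[1], ]
  cm <- confusion_metrics(tp = best$tp, fn = best$fn, fp = best$fp, tn = best$tn)
  structure(list(cutoff = best$threshold,
                 youden_j = cm$youden_j,
                 sensitivity = cm$sensitivity,
                 specificity = cm$specificity,
                 confusion = cm$confusion,
                 positive_class = roc$positive_class,
                 orientation = roc$orientation),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "<cutoff_result> cutoff = %g, J = %.4f (sensitivity %.2f%%, specificity %.2f%%)\n",
    x$cutoff, x$youden_j, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Stratify a cohort at a marker cutoff
#'
#' Splits the cohort into `faa_e3 <= cutoff` and `> cutoff` strata and
#' produces (a) the outcome-by-stratum 2 x 2 table with its chi-square test
#' and (b) per-marker, per-timepoint group summaries with pooled t tests
#' comparing the strata.
#'
#' @param records Cohort data frame with columns `faa_e3`, `prognosis` (or
#'   `gos_level`, dichotomized on the fly) and marker columns
#'   `<marker>_<timepoint>`.
#' @param cutoff Cutoff on the FAA reported (x 10^-3) scale; must lie
#'   within the observed score range and leave both strata non-empty.
#' @param markers Marker column stems to compare (default gfap, s100b,
#'   gaba; silently skips absent columns).
#' @return List with `outcome_table` (2 x 2 counts, outcome x stratum),
#'   `outcome_test` (chi-square `cohort_test`), `marker_tests` (data frame
#'   of group summaries and pooled t results), `n_le`, `n_gt`, `cutoff`.
#' @export
stratify_by_cutoff <- function(records, cutoff,
                               markers = c("gfap", "s100b", "gaba")) {
  records <- as.data.frame(records)
  if (!"faa_e3" %in% names(records)) stop("records need a `faa_e3` column",
                                          call. = FALSE)
  if (!"prognosis" %in% names(records)) {
    if (!"gos_level" %in% names(records)) {
      stop("records need a `prognosis` or `gos_level` column", call. = FALSE)
    }
    records$prognosis <- dichotomize_gos(records$gos_level)
  }
  rng <- range(records$faa_e3)
  if (cutoff < rng[1] || cutoff > rng[2]) {
    stop(sprintf("cutoff %g outside the observed score range [%g, %g]",
                 cutoff, rng[1], rng[2]), call. = FALSE)
  }
  low <- records$faa_e3 <= cutoff
  if (!any(low) || all(low)) {
    stop("cutoff leaves an empty stratum", call. = FALSE)
  }
  stratum <- factor(ifelse(low, "le_cutoff", "gt_cutoff"),
                    levels = c("le_cutoff", "gt_cutoff"))
  prog <- factor(records$prognosis, levels = c("good", "poor"))
  outcome_table <- table(prognosis = prog, stratum = stratum)
  outcome_test <- chi_square_test(unclass(outcome_table))

  rows <- list()
  for (m in markers) {
    for (tp in c("pre", "post")) {
      col <- paste(m, tp, sep = "_")
      if (!col %in% names(records)) next
      v <- records[[col]]
      keep <- !is.na(v)
      g_lo <- v[keep & low]; g_hi <- v[keep & !low]
      tt <- pooled_t_test(x = g_lo, y = g_hi)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, timepoint = tp,
        n_le = length(g_lo), mean_le = mean(g_lo), sd_le = sd(g_lo),
        n_gt = length(g_hi), mean_gt = mean(g_hi), sd_gt = sd(g_hi),
        t = tt$statistic, df = tt$df, p = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(outcome_table = outcome_table, outcome_test = outcome_test,
       marker_tests = if (length(rows)) do.call(rbind, rows) else NULL,
       n_le = sum(low), n_gt = sum(!low), cutoff = cutoff)
}
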