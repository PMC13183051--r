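#' Dichotomize Glasgow Outcome Scale levels into prognosis
#'
#' GOS level V (good recovery / mild disability) is classified as good
#' prognosis; levels I-IV (death through dependence) as poor prognosis.
#'
#' @param gos_level Vector of GOS levels, either integers 1-5 or Roman
#'   numerals "I".."V".
#' @return Factor with levels `c("good", "poor")`.
#' @examples
#' dichotomize_gos(c(5, 1, 4))
#' dichotomize_gos(c("V", "II"))
#' @export
dichotomize_gos <- function(gos_level) {
  if (is.character(gos_level) || is.factor(gos_level)) {
    lev <- match(toupper(as.character(gos_level)), c("I", "II", "III", "IV", "V"))
  } else {
    lev <- as.numeric(gos_level)
  }
  bad <- is.na(lev) | lev != round(lev) | lev < 1 | lev > 5
  if (any(bad)) {
    stop(sprintf("GOS level out of range I-V at position(s) %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  factor(ifelse(lev == 5, "good", "poor"), levels = c("good", "poor"))
}

new_cohort_test <- function(statistic, df, p, method, extra = list()) {
  structure(c(list(statistic = statistic, df = df, p.value = p,
                   method = method), extra),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("<cohort_test> %s: statistic = %.4f, df = %s, p = %.4g\n",
              x$method, x$statistic,
              if (is.na(x$df)) "NA" else format(x$df), x$p.value))
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' Student's t test with pooled variance, computed either from raw vectors
#' `x`, `y` or directly from group summaries (mean, SD, n) — the form in
#' which published cohort tables report their groups. Both routes use the
#' same formula, so a summary computed from a vector gives the identical
#' statistic:
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2`.
#'
#' @param x,y Optional raw numeric vectors (NAs dropped).
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries, used when `x`/`y` are
#'   not supplied.
#' @return A `cohort_test` with the signed t statistic, df, and two-sided p.
#' @examples
#' pooled_t_test(mean1 = 89.10, sd1 = 17.04, n1 = 126,
#'               mean2 = 66.64, sd2 = 17.77, n2 = 51)
#' @export
pooled_t_test <- function(x = NULL, y = NULL,
                          mean1 = NULL, sd1 = NULL, n1 = NULL,
                          mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) stop("supply both x and y", call. = FALSE)
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  if (is.null(mean1) || is.null(sd1) || is.null(n1) ||
      is.null(mean2) || is.null(sd2) || is.null(n2)) {
    stop("supply either raw vectors or complete summaries for both groups",
         call. = FALSE)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative",
                               call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- if (se == 0) 0 else (mean1 - mean2) / se
  p <- 2 * pt(-abs(tstat), df)
  new_cohort_test(tstat, df, p, "t_pooled",
                  list(estimate = c(mean1 = mean1, mean2 = mean2),
                       n = c(n1 = n1, n2 = n2)))
}

#' Pearson chi-square test of independence
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)` — no continuity correction, matching the convention
#' of cohort tables computed on raw counts. Errors when any expected count
#' is zero, in which case the Fisher exact test applies.
#'
#' @param counts Non-negative integer matrix (at least 2 x 2) of observed
#'   counts.
#' @return A `cohort_test` with the chi-square statistic, df, p, and the
#'   expected counts.
#' @examples
#' chi_square_test(matrix(c(42, 84, 29, 22), 2))  # 2x2 counts
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and finite", call. = FALSE)
  }
  n <- sum(counts)
  if (n <= 0) stop("grand total must be positive", call. = FALSE)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  if (any(expected == 0)) {
    stop("zero expected cell count: use fisher_exact_test() instead",
         call. = FALSE)
  }
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  p <- pchisq(stat, df, lower.tail = FALSE)
  new_cohort_test(stat, df, p, "chi_square", list(expected = expected))
}

#' Fisher exact test for a 2 x 2 table
#'
#' Two-sided p by summing the hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one.
#'
#' @param counts A 2 x 2 non-negative integer matrix.
#' @return A `cohort_test` (statistic is `NA`; the test is exact).
#' @export
fisher_exact_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) {
    stop("Fisher exact test requires a 2 x 2 table", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  p <- stats::fisher.test(counts)$p.value
  new_cohort_test(NA_real_, NA_real_, min(p, 1), "fisher")
}

#' Shapiro-Wilk normality test
#'
#' Royston's W statistic and p-value, defined for 3 <= n <= 5000
#' observations with non-zero variance.
#'
#' @param x Numeric vector (NAs dropped).
#' @return A `cohort_test` with the W statistic and p-value.
#' @export
shapiro_wilk_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got n = %d)", n),
         call. = FALSE)
  }
  if (var(x) == 0) {
    stop("Shapiro-Wilk undefined for a constant vector (zero variance)",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  new_cohort_test(unname(sw$statistic), NA_real_, sw$p.value, "shapiro_wilk")
}

logistic_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' Binary logistic regression with Wald inference
#'
#' Maximum-likelihood logistic regression fit by iteratively reweighted
#' least squares (Newton-Raphson with step-halving, so the log-likelihood is
#' non-decreasing across iterations). Convergence is declared when the
#' maximum absolute score falls below `tol_score` or the relative
#' log-likelihood change falls below `tol_loglik`. Per-term output follows
#' the conventional regression-table layout: coefficient, standard error,
#' Wald statistic `(beta/se)^2` (chi-square with 1 df), two-sided p, odds
#' ratio `exp(beta)` and 95% Wald CI `exp(beta +/- 1.96 se)`.
#'
#' @param x Numeric matrix or data frame of covariates (no intercept
#'   column; one is added). Factors/characters are not coded automatically —
#'   supply the coded design.
#' @param y Binary outcome: 0/1 numeric, logical, or a two-level factor
#'   (second level = event).
#' @param max_iter,tol_score,tol_loglik Iteration controls.
#' @return An object of class `logistic_fit`: list with `coefficients` (a
#'   data frame with columns `term`, `beta`, `se`, `wald`, `p`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`), `loglik`, `loglik_path`,
#'   `iterations`, `converged`, `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- rbinom(200, 1, plogis(0.5 - 0.8 * x))
#' fit_logistic(cbind(x = x), y)
#' @export
fit_logistic <- function(x, y, max_iter = 100, tol_score = 1e-8,
                         tol_loglik = 1e-10) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  X <- if (is.null(x)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    as.matrix(cbind("(Intercept)" = 1, x))
  }
  storage.mode(X) <- "double"
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than model terms", call. = FALSE)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (min(sum(y), n - sum(y)) == 0) {
    stop("outcome has a single class; logistic model undefined", call. = FALSE)
  }

  beta <- rep(0, p)
  ll <- logistic_loglik(beta, X, y)
  ll_path <- ll
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- plogis(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e)
      stop("information matrix singular (collinear design?)", call. = FALSE))
    # step-halving guarantees monotone log-likelihood
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- logistic_loglik(cand, X, y)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand
    rel_change <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    ll <- ll_new
    ll_path <- c(ll_path, ll)
    if (max(abs(beta)) > 1e2) {
      stop(paste("complete or quasi-complete separation detected",
                 "(diverging coefficients); logistic MLE does not exist"),
           call. = FALSE)
    }
    if (max(abs(score)) < tol_score || rel_change < tol_loglik) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    stop(sprintf(
      "IRLS did not converge in %d iterations (max |score| = %.3g, loglik = %.6g)",
      max_iter, max(abs(drop(crossprod(X, y - plogis(drop(X %*% beta)))))), ll),
      call. = FALSE)
  }

  mu <- plogis(drop(X %*% beta))
  # under (quasi-)complete separation the score vanishes as |beta| grows,
  # so divergence must be caught on the fitted probabilities as well
  if (ncol(X) > 1 && max(abs(y - mu)) < 1e-3) {
    stop(paste("complete separation detected (all outcomes fitted exactly);",
               "logistic MLE does not exist"), call. = FALSE)
  }
  info <- crossprod(X * (mu * (1 - mu)), X)
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  wald <- (beta / se)^2
  pval <- pchisq(wald, df = 1, lower.tail = FALSE)
  coef_tab <- data.frame(
    term = colnames(X), beta = beta, se = se, wald = wald, p = pval,
    odds_ratio = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = coef_tab, loglik = ll, loglik_path = ll_path,
                 iterations = iter, converged = converged, n = n,
                 vcov = vcov),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, loglik = %.4f, %d IRLS iterations\n",
              x$n, x$loglik, x$iterations))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Sample size for estimating a proportion
#'
#' `N = z_{alpha/2}^2 * pi * (1 - pi) / delta^2`: the minimum sample size to
#' estimate a population proportion `pi` within an allowable error `delta`
#' at two-sided level `alpha`.
#'
#' @param pi Anticipated proportion in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param delta Allowable absolute error (> 0).
#' @return List with `raw` (formula value) and `n` (rounded up).
#' @examples
#' sample_size(pi = 0.139, alpha = 0.05, delta = 0.06)
#' @export
sample_size <- function(pi, alpha = 0.05, delta) {
  if (!(pi > 0 && pi < 1)) stop_invalid("pi", "must lie in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop_invalid("alpha", "must lie in (0, 1)")
  if (!(delta > 0)) stop_invalid("delta", "must be positive")
  z <- qnorm(1 - alpha / 2)
  raw <- z^2 * pi * (1 - pi) / delta^2
  list(raw = raw, n = ceiling(raw))
}

#' Inflate a sample size for anticipated dropout
#'
#' @param n Base sample size.
#' @param dropout Anticipated dropout fraction (default 0.2, i.e. +20%).
#' @return Inflated sample size, rounded up.
#' @export
inflate_for_dropout <- function(n, dropout = 0.2) {
  if (dropout < 0) stop_invalid("dropout", "must be non-negative")
  ceiling(n * (1 + dropout))
}
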