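test_that("GOS dichotomization: only level V is a good prognosis", {
  expect_equal(as.character(dichotomize_gos(5)), "good")
  expect_equal(as.character(dichotomize_gos(1)), "poor")
  expect_equal(as.character(dichotomize_gos(4)), "poor")
  expect_equal(as.character(dichotomize_gos(c("V", "II", "IV"))),
               c("good", "poor", "poor"))
  expect_error(dichotomize_gos(6), "out of range")
  expect_error(dichotomize_gos("VI"), "out of range")
  expect_error(dichotomize_gos(0), "out of range")
})

test_that("pooled t test agrees with t.test and its own summary route", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ours <- pooled_t_test(x = x, y = y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    # summary route is exactly the vector route
    via_sum <- pooled_t_test(mean1 = mean(x), sd1 = sd(x), n1 = length(x),
                             mean2 = mean(y), sd2 = sd(y), n2 = length(y))
    expect_identical(ours$statistic, via_sum$statistic)
  }
  null_case <- pooled_t_test(mean1 = 3, sd1 = 1, n1 = 10,
                             mean2 = 3, sd2 = 1, n2 = 10)
  expect_equal(null_case$statistic, 0)
  expect_equal(null_case$p.value, 1)
  expect_error(pooled_t_test(mean1 = 1, sd1 = 1, n1 = 1,
                             mean2 = 2, sd2 = 1, n2 = 5), "n >= 2")
})

test_that("Pearson chi-square matches chisq.test without correction", {
  set.seed(22)
  for (i in 1:20) {
    r <- sample(2:4, 1); cc <- sample(2:3, 1)
    tab <- matrix(rpois(r * cc, 20) + 1, r, cc)
    ours <- chi_square_test(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
  # identical row proportions -> exact independence
  expect_equal(chi_square_test(matrix(c(10, 20, 30, 60), 2))$statistic, 0)
  expect_error(chi_square_test(matrix(c(5, 0, 7, 0), 2)), "[Ff]isher")
  expect_error(chi_square_test(matrix(1:3, 3, 1)), "2 x 2")
})

test_that("Fisher exact two-sided p equals the enumeration oracle", {
  expect_equal(fisher_exact_test(matrix(c(1, 11, 9, 3), 2))$p.value,
               oracle_fisher_p(matrix(c(1, 11, 9, 3), 2)), tolerance = 1e-12)
  expect_equal(fisher_exact_test(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  expect_equal(fisher_exact_test(matrix(c(0, 0, 4, 6), 2))$p.value, 1)
  set.seed(23)
  for (i in 1:40) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_test(matrix(1:6, 2)), "2 x 2")
})

test_that("logistic regression: closed-form intercept and oracle agreement", {
  y <- rep(c(1, 0), c(51, 126))
  fit0 <- fit_logistic(NULL, y)
  expect_equal(fit0$coefficients$beta, log(51 / 126), tolerance = 1e-8)

  # 20-row fixture vs independent quasi-Newton maximizer and vs glm
  set.seed(24)
  x20 <- cbind(a = rnorm(20), b = rbinom(20, 1, 0.5))
  y20 <- rbinom(20, 1, plogis(0.3 + 0.8 * x20[, "a"] - 0.5 * x20[, "b"]))
  fit <- fit_logistic(x20, y20)
  expect_lt(max(abs(fit$coefficients$beta - oracle_logistic(x20, y20))), 1e-6)
  ref <- glm(y20 ~ x20, family = binomial)
  expect_equal(fit$coefficients$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("logistic fit: monotone log-likelihood, tiny score, exact table rules", {
  set.seed(25)
  x <- cbind(v = rnorm(300), w = runif(300))
  y <- rbinom(300, 1, plogis(-0.5 + 1.2 * x[, "v"]))
  fit <- fit_logistic(x, y)
  expect_true(all(diff(fit$loglik_path) >= -1e-9))
  X <- cbind(1, x)
  score <- crossprod(X, y - plogis(drop(X %*% fit$coefficients$beta)))
  expect_lt(max(abs(score)), 1e-6)
  co <- fit$coefficients
  expect_identical(co$odds_ratio, exp(co$beta))
  expect_identical(co$wald, (co$beta / co$se)^2)
  expect_identical(co$ci_lower, exp(co$beta - 1.96 * co$se))
  expect_identical(co$ci_upper, exp(co$beta + 1.96 * co$se))
  expect_true(all(co$ci_lower < co$odds_ratio & co$odds_ratio < co$ci_upper))
})

test_that("logistic fit rejects separation and degenerate outcomes", {
  x <- cbind(z = c(-(10:1), 1:10))
  expect_error(fit_logistic(x, as.integer(x[, 1] > 0)), "separation")
  expect_error(fit_logistic(cbind(rnorm(10)), rep(1, 10)), "single class")
  expect_error(fit_logistic(cbind(rnorm(10)), c(rep(0:1, 4), 2, 0)), "binary")
})

test_that("Shapiro-Wilk wrapper: calibration, power, and domain errors", {
  set.seed(26)
  expect_gt(shapiro_wilk_test(rnorm(5000))$p.value, 0.01)
  set.seed(27)
  expect_lt(shapiro_wilk_test(rexp(100))$p.value, 0.01)
  expect_error(shapiro_wilk_test(rep(1, 10)), "constant")
  expect_error(shapiro_wilk_test(rnorm(2)), "3 <= n <= 5000")
  expect_error(shapiro_wilk_test(rnorm(5001)), "3 <= n <= 5000")
})

test_that("proportion sample-size formula and its scaling laws", {
  res <- sample_size(pi = 0.139, alpha = 0.05, delta = 0.06)
  z <- qnorm(0.975)
  expect_equal(res$raw, z^2 * 0.139 * 0.861 / 0.06^2, tolerance = 1e-12)
  expect_equal(res$raw, 127.7, tolerance = 0.01)
  expect_equal(res$n, 128)
  # doubling the allowable error divides N by 4
  expect_equal(sample_size(0.139, 0.05, 0.12)$raw, res$raw / 4,
               tolerance = 1e-12)
  # pi = 0.5 maximizes N
  ns <- vapply(seq(0.05, 0.95, by = 0.05),
               function(p) sample_size(p, 0.05, 0.06)$raw, numeric(1))
  expect_equal(which.max(ns), 10L)  # pi = 0.5
  expect_equal(inflate_for_dropout(126, 0.2), 152)
  expect_error(sample_size(0, 0.05, 0.06), "pi")
  expect_error(sample_size(0.2, 0.05, 0), "delta")
})
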