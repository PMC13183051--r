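# Independent oracles, written as plain brute-force code so they share no
# implementation with the package paths they check.

# Welch oracle: explicit per-window loop, scalar sums, periodic Hann.
oracle_welch <- function(x, fs, window_s = 2, overlap = 0.5,
                         starts = NULL) {
  L <- round(window_s * fs)
  hop <- max(1, round(L * (1 - overlap)))
  if (is.null(starts)) starts <- seq(1, length(x) - L + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  u <- sum(w^2)
  n_f <- L %/% 2 + 1
  acc <- numeric(n_f)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- fft(seg)[1:n_f]
    p <- Mod(sp)^2 / (fs * u)
    last_dbl <- if (L %% 2 == 0) n_f - 1 else n_f
    p[2:last_dbl] <- 2 * p[2:last_dbl]
    acc <- acc + p
  }
  list(freqs = (0:(n_f - 1)) * fs / L, psd = acc / length(starts))
}

# Fisher two-sided p by full hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Logistic MLE by quasi-Newton maximization of the log-likelihood with an
# analytic gradient (no IRLS).
oracle_logistic <- function(x, y) {
  X <- cbind(1, as.matrix(x))
  negll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) -drop(crossprod(X, y - plogis(drop(X %*% b))))
  fit <- optim(rep(0, ncol(X)), negll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-16))
  fit$par
}

# Mann-Whitney AUC: explicit pair count, half weight for ties. With the
# lower_score_positive orientation a positive "wins" when its score is
# below the negative's.
oracle_mw_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  u <- 0
  for (a in sp) for (b in sn) {
    u <- u + if (a < b) 1 else if (a == b) 0.5 else 0
  }
  u / (length(sp) * length(sn))
}

# Exhaustive Youden search over every observed threshold, with the
# max-J -> max-sensitivity -> lower-cutoff tie rule.
oracle_youden <- function(scores, is_pos) {
  best <- NULL
  for (t in sort(unique(scores))) {
    call_pos <- scores <= t
    sens <- sum(call_pos & is_pos) / sum(is_pos)
    spec <- sum(!call_pos & !is_pos) / sum(!is_pos)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-15 ||
        (abs(j - best$j) <= 1e-15 && sens > best$sens + 1e-15)) {
      best <- list(cutoff = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# Steady-state amplitude of a (near-)sinusoidal signal: peak of the middle
# half, away from filter edge transients.
steady_amplitude <- function(y) {
  n <- length(y)
  max(abs(y[(n %/% 4):(3 * n %/% 4)]))
}

make_rec <- function(samples, fs = 500, labels = NULL) {
  if (is.null(labels)) labels <- colnames(samples)
  eeg_recording(as.matrix(samples), fs = fs, channel_labels = labels)
}
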