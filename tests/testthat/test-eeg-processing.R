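test_that("common average reference zeroes the scalp mean and is idempotent", {
  # hand-computed toy: columns are channels F3, F4, Cz
  m <- cbind(F3 = c(1, 2, 3, 4), F4 = c(5, 6, 7, 8), Cz = c(0, 3, 2, 0))
  rec <- make_rec(m, fs = 10)
  out <- rereference_common_average(rec)
  row_means <- rowMeans(m)
  expect_equal(out$samples, m - row_means %o% rep(1, 3),
               ignore_attr = TRUE)
  expect_true(all(abs(rowMeans(out$samples)) < 1e-9))

  # constant channels collapse to zero
  const <- make_rec(cbind(F3 = rep(7, 5), F4 = rep(7, 5), Cz = rep(7, 5)), fs = 10)
  expect_true(all(rereference_common_average(const)$samples == 0))

  # idempotence
  set.seed(1)
  r <- make_rec(cbind(F3 = rnorm(50), F4 = rnorm(50), Cz = rnorm(50)), fs = 10)
  once <- rereference_common_average(r)
  twice <- rereference_common_average(once)
  expect_equal(twice$samples, once$samples, tolerance = 1e-12)
})

test_that("EOG channels are excluded from the common average and preserved", {
  set.seed(2)
  m <- cbind(F3 = rnorm(20), F4 = rnorm(20), Cz = rnorm(20),
             VEOG = rnorm(20) * 100)
  rec <- make_rec(m, fs = 10)
  out <- rereference_common_average(rec)
  expect_equal(out$samples[, "VEOG"], m[, "VEOG"], ignore_attr = TRUE)
  scalp_mean <- rowMeans(m[, 1:3])
  expect_equal(out$samples[, "F3"], m[, "F3"] - scalp_mean, ignore_attr = TRUE)
  # a single scalp channel has no defined average reference
  solo <- make_rec(cbind(F3 = rnorm(10), VEOG = rnorm(10)), fs = 10)
  expect_error(rereference_common_average(solo), "fewer than 2")
})

test_that("zero-phase bandpass passes alpha and rejects DC and 60 Hz", {
  fs <- 500
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  mk <- function(x) make_rec(cbind(F3 = x, F4 = x), fs = fs)
  a10 <- steady_amplitude(channel_data(bandpass(mk(sin(2 * pi * 10 * tt))), "F3"))
  expect_gt(a10, 0.99)
  expect_lt(a10, 1.01)
  a60 <- steady_amplitude(channel_data(bandpass(mk(sin(2 * pi * 60 * tt))), "F3"))
  expect_lte(a60, 0.05)
  adc <- steady_amplitude(channel_data(bandpass(mk(rep(1, length(tt)))), "F3"))
  expect_lte(adc, 0.05)
  expect_error(bandpass(mk(sin(tt)), low = 0.3, high = 300), "fs/2")
  expect_error(bandpass(mk(sin(tt)), low = 0, high = 40), "0 < low")
})

test_that("artifact rejection masks injected bursts with padding, nothing else", {
  fs <- 500
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  clean <- 10 * sin(2 * pi * 10 * tt)
  rec <- make_rec(cbind(F3 = clean, F4 = clean), fs = fs)
  out <- reject_artifacts(rec, z_threshold = 8, pad_s = 0.2)
  expect_false(any(out$artifact_mask))

  burst_idx <- 2000:2050
  dirty <- clean
  dirty[burst_idx] <- dirty[burst_idx] + 500
  rec2 <- make_rec(cbind(F3 = dirty, F4 = clean), fs = fs)
  out2 <- reject_artifacts(rec2, z_threshold = 8, pad_s = 0.2)
  pad <- round(0.2 * fs)
  expect_true(all(out2$artifact_mask[(min(burst_idx) - pad):(max(burst_idx) + pad)]))
  expect_false(any(out2$artifact_mask[1:(min(burst_idx) - pad - 200)]))
  expect_false(any(out2$artifact_mask[(max(burst_idx) + pad + 200):length(clean)]))

  # everything over threshold -> no clean data left
  loud <- make_rec(cbind(F3 = rep(c(-1000, 1000), 500),
                         F4 = rep(c(-1000, 1000), 500)), fs = fs)
  expect_error(reject_artifacts(loud, z_threshold = 1e-4), "no clean data")
})

test_that("rejecting blink and burst artifacts moves the recovered FAA toward its target", {
  target <- 0.0891
  errs <- vapply(1:50, function(s) {
    rec <- generate_eeg(eeg_synthesis_spec(
      target_faa = target, duration_s = 40, noise_sd = 1, blink_rate = 15,
      artifact_rate = 6, seed = s))
    with_rej <- faa_from_recording(rec, reject = TRUE)$faa_ratio
    without <- faa_from_recording(rec, reject = FALSE)$faa_ratio
    c(abs(with_rej - target), abs(without - target))
  }, numeric(2))
  expect_lt(median(errs[1, ]), median(errs[2, ]))
})

test_that("Welch PSD satisfies Parseval and matches the brute-force oracle", {
  fs <- 500
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * tt)
  rec <- make_rec(cbind(F3 = x, F4 = 2 * x), fs = fs)
  sp <- welch_psd(rec)
  df <- sp$freqs[2] - sp$freqs[1]
  band_power <- sum(sp$psd[sp$freqs >= 8 & sp$freqs <= 13, "F3"]) * df
  expect_equal(band_power, 0.5, tolerance = 0.05)

  set.seed(3)
  y <- rnorm(length(tt))
  rec2 <- make_rec(cbind(F3 = y, F4 = y), fs = fs)
  sp2 <- welch_psd(rec2)
  or <- oracle_welch(y, fs)
  expect_equal(sp2$freqs, or$freqs, tolerance = 1e-12)
  expect_lt(max(abs(sp2$psd[, "F3"] - or$psd) / pmax(or$psd, 1e-300)), 1e-9)

  z <- make_rec(cbind(F3 = rep(0, 5000), F4 = rep(0, 5000)), fs = fs)
  expect_true(all(welch_psd(z)$psd == 0))
})

test_that("Welch drops windows overlapping masked samples", {
  fs <- 100
  set.seed(4)
  y <- rnorm(20 * fs)
  mask <- rep(FALSE, length(y))
  mask[701:950] <- TRUE
  rec <- eeg_recording(cbind(F3 = y, F4 = y), fs = fs,
                       artifact_mask = mask)
  sp <- welch_psd(rec, window_s = 2, overlap = 0.5)
  L <- 2 * fs; hop <- L / 2
  starts <- seq(1, length(y) - L + 1, by = hop)
  clean <- starts[vapply(starts, function(s0) !any(mask[s0:(s0 + L - 1)]),
                         logical(1))]
  expect_equal(sp$n_windows, length(clean))
  or <- oracle_welch(y, fs, starts = clean)
  expect_lt(max(abs(sp$psd[, "F3"] - or$psd) / pmax(or$psd, 1e-300)), 1e-9)

  short <- make_rec(cbind(F3 = rnorm(250), F4 = rnorm(250)), fs = 100)
  expect_error(welch_psd(short, window_s = 2), "insufficient clean data")
})

test_that("split halves of white noise give statistically matching spectra", {
  fs <- 200
  n_ok <- 0
  for (s in 1:40) {
    set.seed(s + 100)
    y <- rnorm(16 * fs)
    h1 <- welch_psd(make_rec(cbind(F3 = y[1:(8 * fs)], F4 = y[1:(8 * fs)]),
                             fs = fs))
    h2 <- welch_psd(make_rec(cbind(F3 = y[(8 * fs + 1):(16 * fs)],
                                   F4 = y[(8 * fs + 1):(16 * fs)]), fs = fs))
    # every second bin: adjacent Welch bins are correlated through the
    # Hann window, which would make the nominal KS level anti-conservative
    sel <- seq(3, length(h1$freqs), by = 2)
    p <- suppressWarnings(
      ks.test(log(h1$psd[sel, "F3"]), log(h2$psd[sel, "F3"]))$p.value)
    n_ok <- n_ok + (p > 0.01)
  }
  expect_gte(n_ok, 38)
})

test_that("alpha-band power is the inclusive in-band mean of the PSD", {
  mk_spec <- function(freqs, psd) {
    structure(list(freqs = freqs, psd = cbind(F3 = psd),
                   channel_labels = "F3", n_windows = 1, fs = 100,
                   method_params = list()), class = "spectral_estimate")
  }
  grid <- seq(0, 20, by = 1)
  expect_equal(alpha_band_power(mk_spec(grid, rep(3.5, length(grid))), "F3"), 3.5)

  psd <- rep(0, length(grid))
  psd[grid == 10] <- 1       # 6 in-band grid points: 8..13
  expect_equal(alpha_band_power(mk_spec(grid, psd), "F3"), 1 / 6)

  low_grid <- seq(0, 6, by = 1)
  expect_error(alpha_band_power(mk_spec(low_grid, rep(1, 7)), "F3"),
               "does not cover")
  expect_error(alpha_band_power(mk_spec(grid, psd), "Pz"), "not present")
})

test_that("FAA index: definition, antisymmetry, bounds, scale invariance", {
  expect_equal(compute_faa(5, 5)$ratio, 0)
  expect_equal(compute_faa(5, 5)$reported, 0)
  expect_equal(compute_faa(1, 2)$ratio, 1 / 3)
  expect_equal(compute_faa(1, 2)$reported, 1000 / 3)
  expect_error(compute_faa(0, 0), "undefined")
  expect_error(compute_faa(-1, 2), "non-negative")

  set.seed(5)
  for (i in 1:200) {
    a <- rexp(1); b <- rexp(1)
    f <- compute_faa(a, b)
    expect_identical(f$ratio, -compute_faa(b, a)$ratio)   # antisymmetry
    expect_true(abs(f$ratio) <= 1)                        # bounded
    expect_identical(f$reported, 1000 * f$ratio)
    k <- runif(1, 0.1, 10)                                # scale invariance
    expect_lt(abs(compute_faa(k * a, k * b)$ratio - f$ratio), 1e-9)
  }
  expect_equal(compute_faa(0, 3)$ratio, 1)   # extremes only at zero power
  expect_equal(compute_faa(3, 0)$ratio, -1)
})
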