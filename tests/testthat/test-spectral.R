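test_that("Welch spectrum finds a pure tone and is Parseval-consistent", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- cbind(tone = sin(2 * pi * 10 * t))
  psd <- compute_psd(x, window_length = 2, fs = fs)
  expect_equal(psd$freqs[which.max(psd$power)], 10)
  # Parseval: integrated density ~ signal variance (Hann-windowed Welch)
  tot <- sum(psd$power) * diff(psd$freqs[1:2])
  expect_lt(abs(tot - var(x[, 1])) / var(x[, 1]), 0.05)
})

test_that("white noise gives a flat spectrum within sampling error", {
  set.seed(5)
  x <- cbind(rnorm(250 * 120))
  psd <- compute_psd(x, fs = 250)
  sel <- psd$freqs >= 5 & psd$freqs <= 100
  p <- psd$power[sel, 1]
  expect_lt(sd(p) / mean(p), 0.15)
  expect_error(compute_psd(x, overlap = 0.95, fs = 250), "overlap")
})

test_that("Welch estimate matches the generating model across the fit range", {
  m <- mci_model()
  rec <- synthesize_recording(m, montage("O1", 250), 120, seed = 9)
  psd <- compute_psd(rec)
  sel <- psd$freqs >= 1 & psd$freqs <= 40
  truth <- evaluate_model_psd(m, psd$freqs[sel])
  rel <- psd$power[sel, 1] / truth
  expect_lt(abs(median(rel) - 1), 0.1)
})

test_that("aperiodic fit is exact on noiseless closed-form input", {
  f <- seq(1, 40, by = 0.5)
  psd <- make_psd(f, 2 / f)            # k = 2, x = 1
  fit <- fit_aperiodic(psd)
  expect_equal(fit$exponent, 1.0, tolerance = 1e-6)
  expect_equal(fit$offset, 2.0, tolerance = 1e-6)
  expect_gt(fit$goodness, 0.999)

  flat <- fit_aperiodic(make_psd(f, rep(3, length(f))))
  expect_equal(flat$exponent, 0.0, tolerance = 1e-6)

  expect_error(fit_aperiodic(make_psd(f[1:5], 1 / f[1:5]), fit_range = c(1, 3)),
               "10 usable bins")
})

test_that("aperiodic exponent recovers from noisy generated data with a peak", {
  errs <- vapply(1:5, function(s) {
    rec <- alpha_recording(x = 1.5, seed = s, channels = "O1")
    fit <- fit_aperiodic(compute_psd(rec))
    fit$exponent - 1.5
  }, numeric(1))
  expect_true(all(abs(errs) < 0.15))
})

test_that("peak extraction recovers one and two generated peaks", {
  # noiseless: empty flattened spectrum -> no peaks
  f <- seq(1, 40, by = 0.5)
  psd0 <- make_psd(f, 5 / f)
  fit0 <- fit_aperiodic(psd0)
  ps0 <- extract_peaks(psd0, fit0, min_amplitude = 0.05)
  expect_length(ps0$peaks, 0)

  rec1 <- alpha_recording(iapf = 10, seed = 2, channels = "O1")
  psd1 <- compute_psd(rec1)
  ps1 <- extract_peaks(psd1, fit_aperiodic(psd1))
  expect_lt(abs(peak_in_band(ps1, c(7, 13)) - 10), 0.25)

  m2 <- spectral_model(0.02, 5, 1.2, list(gaussian_peak(6, 1.2, 0.8),
                                          gaussian_peak(10, 1.5, 0.8)))
  rec2 <- synthesize_recording(m2, montage("O1", 250), 120, seed = 4)
  psd2 <- compute_psd(rec2)
  ps2 <- extract_peaks(psd2, fit_aperiodic(psd2))
  centers <- vapply(ps2$peaks, `[[`, numeric(1), "center_freq")
  expect_lt(min(abs(centers - 6)), 0.25)
  expect_lt(min(abs(centers - 10)), 0.25)
})

test_that("joint model refinement reproduces a noiseless model", {
  truth <- spectral_model(0.05, 4, 1.3, list(gaussian_peak(10, 1.5, 0.9)))
  psd <- model_psd_fixture(truth, seq(1, 40, by = 0.25))
  fit <- fit_spectral_model(psd)
  expect_equal(fit$aperiodic_exponent, 1.3, tolerance = 0.01)
  expect_equal(model_peak_in_band(fit), 10, tolerance = 0.01)
  expect_gt(attr(fit, "goodness"), 0.999)
})

test_that("center-of-gravity i-APF respects symmetry and hand weighting", {
  f <- seq(7, 13, by = 0.01)
  sym <- make_psd(f, exp(-(f - 10)^2 / 2))
  ps_sym <- structure(list(peaks = list(),
                           flattened = list(freqs = f, power = sym$power[, 1]),
                           channel = 1L), class = "peak_set")
  expect_equal(iapf_center_of_gravity(ps_sym)$value, 10.0, tolerance = 1e-9)

  two <- exp(-(f - 9)^2 / (2 * 0.25^2)) + exp(-(f - 11)^2 / (2 * 0.25^2))
  ps_two <- structure(list(peaks = list(),
                           flattened = list(freqs = f, power = two),
                           channel = 1L), class = "peak_set")
  expect_equal(iapf_center_of_gravity(ps_two)$value, 10.0, tolerance = 1e-6)

  # idealized two-bin reduction: (3*9 + 1*11) / 4 = 9.5
  bins <- c(9, 11)
  ps_bins <- structure(list(peaks = list(),
                            flattened = list(freqs = bins, power = c(3, 1)),
                            channel = 1L), class = "peak_set")
  expect_equal(iapf_center_of_gravity(ps_bins)$value, 9.5)

  # full-grid value against a brute-force summation oracle
  w <- 3 * exp(-(f - 9)^2 / (2 * 0.25^2)) + 1 * exp(-(f - 11)^2 / (2 * 0.25^2))
  ps_full <- structure(list(peaks = list(),
                            flattened = list(freqs = f, power = w),
                            channel = 1L), class = "peak_set")
  oracle <- sum(f * w) / sum(w)
  expect_equal(iapf_center_of_gravity(ps_full)$value, oracle)

  ps_zero <- structure(list(peaks = list(),
                            flattened = list(freqs = f, power = rep(0, length(f))),
                            channel = 1L), class = "peak_set")
  expect_error(iapf_center_of_gravity(ps_zero), "no alpha rhythm")
})

test_that("top-3 posterior-node averaging follows the clinical rule", {
  all10 <- setNames(rep(10, 6), c("O1", "O2", "Oz", "P3", "P4", "Pz"))
  expect_equal(iapf_top3_average(all10)$value, 10.0)

  mixed <- setNames(c(9.5, 9.8, 10.1, 8.0, 8.2, 8.4),
                    c("O1", "O2", "Oz", "P3", "P4", "Pz"))
  expect_equal(iapf_top3_average(mixed)$value, (10.1 + 9.8 + 9.5) / 3)

  three <- setNames(c(9, 10, 11), c("O1", "O2", "Pz"))
  expect_equal(iapf_top3_average(three)$value, 10.0)

  two <- setNames(c(9, 10), c("O1", "O2"))
  expect_error(iapf_top3_average(two), "center-of-gravity")
})

test_that("band power integrates the density (trapezoid)", {
  f <- seq(1, 40, by = 0.5)
  expect_equal(unname(band_power(make_psd(f, rep(0, length(f))), c(8, 12))), 0)
  expect_equal(unname(band_power(make_psd(f, rep(1, length(f))), c(8, 12))), 4.0)

  # Gaussian-peak area against the closed form
  m <- spectral_model(0, 0.001, 0.01, list(gaussian_peak(10, 2, 0.6)))
  fg <- seq(5, 15, by = 0.01)
  bp <- unname(band_power(make_psd(fg, evaluate_model_psd(m, fg)), c(5, 15)))
  analytic <- 2 * 0.6 * sqrt(2 * pi) + sum(0.001 * 10^(-0.01)) * 10
  expect_equal(bp, analytic, tolerance = 0.01)
})

test_that("power ratio behaves as the controller's y signal", {
  f <- seq(1, 40, by = 0.5)
  flat <- make_psd(f, rep(1, length(f)))
  expect_equal(unname(power_ratio(flat, c(4, 8), c(8, 12))), 1.0)

  m_mci <- mci_model(theta_amplitude = 1.2, alpha_amplitude = 0.6)
  m_heal <- healthy_model()
  p_mci <- make_psd(f, evaluate_model_psd(m_mci, f))
  p_heal <- make_psd(f, evaluate_model_psd(m_heal, f))
  r_mci <- power_ratio(p_mci, c(4, 8), c(8, 13))
  r_heal <- power_ratio(p_heal, c(4, 8), c(8, 13))
  expect_gt(unname(r_mci), unname(r_heal))
})

test_that("coherence is bounded, symmetric, and separates shared vs independent sources", {
  rec <- alpha_recording(seed = 6, channels = c("A", "B"), duration = 60)
  self <- rec
  self$samples <- cbind(A = rec$samples[, 1], B = rec$samples[, 1])
  expect_equal(coherence(self, "A", "B"), 1.0, tolerance = 1e-9)

  indep <- coherence(rec, "A", "B")     # channels drawn independently
  expect_lt(indep, 0.2)

  set.seed(8)
  n <- 60 * 250
  common <- sin(2 * pi * 10 * seq_len(n) / 250)
  shared <- rec
  shared$samples <- cbind(A = common + rnorm(n), B = common + rnorm(n))
  mid <- coherence(shared, "A", "B", band = c(9, 11))
  expect_gt(mid, indep)
  expect_lt(mid, 1)
  expect_equal(coherence(shared, "A", "B"), coherence(shared, "B", "A"))
  expect_error(coherence(rec, "A", "A"), "distinct")
})

test_that("aperiodic/periodic separation is idempotent", {
  m <- spectral_model(0.5, 5, 1.5, list(gaussian_peak(10, 1.5, 0.8)))
  rec <- synthesize_recording(m, montage("O1", 250), 120, seed = 12)
  psd <- compute_psd(rec)
  fit <- fit_aperiodic(psd)
  # remove only the 1/f part; what remains (floor + peak) has no slope
  sel <- psd$freqs >= 1 & psd$freqs <= 40
  resid <- psd$power[sel, 1] - fit$offset * psd$freqs[sel]^(-fit$exponent)
  psd2 <- make_psd(psd$freqs[sel], pmax(resid, 1e-6))
  refit <- fit_aperiodic(psd2)
  expect_lt(abs(refit$exponent), 0.1)
})

test_that("the two i-APF estimators agree on single-peak subjects", {
  mt <- montage(c("O1", "O2", "Oz", "P3", "P4", "Pz"), 250)
  m <- spectral_model(0.02, 5, 1.3, list(gaussian_peak(9.6, 1.5, 0.8)))
  rec <- synthesize_recording(m, mt, 120, seed = 21)
  psd <- compute_psd(rec)
  peaks <- cogs <- setNames(rep(NA_real_, 6), mt$channel_labels)
  for (j in 1:6) {
    ap <- fit_aperiodic(psd, channel = j)
    ps <- extract_peaks(psd, ap)
    peaks[j] <- peak_in_band(ps, c(7, 13))
    cogs[j] <- iapf_center_of_gravity(ps)$value
  }
  top3 <- iapf_top3_average(peaks)$value
  expect_lt(abs(top3 - mean(cogs)), 0.3)
})
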