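# Shared fixtures: hand-built spectra and small random nets.

# A power_spectrum object from explicit freq/power vectors.
make_psd <- function(freqs, power, fs = 250) {
  structure(
    list(freqs = freqs, power = as.matrix(power), window_length = NA,
         overlap = NA, fs = fs, n_segments = 1L),
    class = "power_spectrum"
  )
}

# Evaluate a model on a grid and wrap it as a noiseless spectrum.
model_psd_fixture <- function(model, freqs = seq(1, 40, by = 0.5)) {
  make_psd(freqs, evaluate_model_psd(model, freqs))
}

# Random symmetric zero-diagonal Hopfield net.
random_hopfield <- function(n, seed, threshold_sd = 0.2) {
  set.seed(seed)
  w <- matrix(rnorm(n^2), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  hopfield_net(w, sample(c(-1, 1), n, replace = TRUE),
               rnorm(n, sd = threshold_sd))
}

# Single-alpha-peak recording for recovery tests.
alpha_recording <- function(iapf = 10, amp = 1.5, x = 1.5, duration = 120,
                            seed = 1, channels = c("O1", "O2")) {
  m <- spectral_model(0.02, 5, x, list(gaussian_peak(iapf, amp, 0.8)))
  synthesize_recording(m, montage(channels, 250), duration, seed = seed)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
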