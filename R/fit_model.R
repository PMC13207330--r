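#' Pool a multichannel spectrum into one average spectrum
#'
#' Averages the power spectral density across channels (valid when the
#' channels share the same generative spectrum, e.g. a homogeneous
#' synthetic montage, or as a montage-average posterior spectrum).
#'
#' @param spectrum A `power_spectrum`.
#' @param channels Optional subset of channel labels/indices.
#' @return A single-channel `power_spectrum` named `"pooled"`.
#' @export
pool_channels <- function(spectrum, channels = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  p <- spectrum$power
  if (!is.null(channels)) p <- p[, channels, drop = FALSE]
  spectrum$power <- matrix(rowMeans(p), ncol = 1,
                           dimnames = list(NULL, "pooled"))
  spectrum
}

#' Joint fit of the full spectral model
#'
#' Refines the sequential aperiodic-then-peaks decomposition by fitting
#' all parameters of `P(f) = L + k f^(-x) + sum_i a_i exp(...)`
#' simultaneously by Levenberg-Marquardt least squares on the log power.
#' The joint fit removes the small centre bias the sequential pass
#' inherits from the sloping aperiodic background beneath each peak.
#'
#' @param spectrum A `power_spectrum` (single channel, or pass `channel`).
#' @param fit_range Frequency range in Hz (default 1-40).
#' @param channel Channel index or label (default 1).
#' @param max_peaks,min_amplitude Passed to the initializing
#'   [extract_peaks()] call.
#' @return A [spectral_model()] with an attribute `"goodness"` (R^2 on
#'   log power over the fit range).
#' @export
fit_spectral_model <- function(spectrum, fit_range = c(1, 40), channel = 1L,
                               max_peaks = 4L, min_amplitude = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  ap <- fit_aperiodic(spectrum, fit_range, channel)
  ps <- extract_peaks(spectrum, ap, max_peaks = max_peaks,
                      min_amplitude = min_amplitude)
  sel <- spectrum$freqs >= fit_range[1] & spectrum$freqs <= fit_range[2]
  f <- spectrum$freqs[sel]
  p <- spectrum$power[sel, channel]
  keep <- p > 0
  f <- f[keep]; lp <- log(p[keep])

  # Edge peaks are fit-range artefacts; only interior peaks are refined.
  pks <- Filter(function(pk) {
    pk$center_freq > fit_range[1] + 1 && pk$center_freq < fit_range[2] - 1
  }, ps$peaks)
  n <- length(pks)

  par0 <- c(max(ap$noise_floor, 1e-6), ap$offset, ap$exponent,
            vapply(pks, `[[`, numeric(1), "amplitude"),
            vapply(pks, `[[`, numeric(1), "center_freq"),
            vapply(pks, `[[`, numeric(1), "bandwidth_sd"))
  model_of <- function(par) {
    v <- par[1] + par[2] * f^(-par[3])
    for (i in seq_len(n)) {
      v <- v + par[3 + i] *
        exp(-(f - par[3 + n + i])^2 / (2 * par[3 + 2 * n + i]^2))
    }
    v
  }
  res_fn <- function(par) log(pmax(model_of(par), 1e-300)) - lp
  lower <- c(0, 1e-12, 0, rep(0, n), rep(min(f) + 0.5, n), rep(0.2, n))
  upper <- c(Inf, Inf, 10, rep(Inf, n), rep(max(f) - 0.5, n), rep(6, n))
  out <- tryCatch(
    minpack.lm::nls.lm(par0, lower, upper, fn = res_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  par <- if (is.null(out)) par0 else out$par

  peaks <- lapply(seq_len(n), function(i) {
    gaussian_peak(par[3 + n + i], par[3 + i], par[3 + 2 * n + i])
  })
  model <- spectral_model(par[1], par[2], par[3], peaks)
  r <- res_fn(par)
  ss_tot <- sum((lp - mean(lp))^2)
  attr(model, "goodness") <- if (ss_tot > 0) max(0, 1 - sum(r^2) / ss_tot) else 1
  model
}

#' Alpha-band peak centre of a fitted spectral model
#'
#' @param model A [spectral_model()] (typically from
#'   [fit_spectral_model()]).
#' @param band Alpha band in Hz.
#' @return Centre in Hz of the highest-amplitude peak inside the band, or
#'   `NA_real_`.
#' @export
model_peak_in_band <- function(model, band = c(7, 13)) {
  stopifnot(inherits(model, "spectral_model"))
  cand <- Filter(function(p) {
    p$center_freq >= band[1] && p$center_freq <= band[2]
  }, model$peaks)
  if (!length(cand)) return(NA_real_)
  amps <- vapply(cand, `[[`, numeric(1), "amplitude")
  cand[[which.max(amps)]]$center_freq
}
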