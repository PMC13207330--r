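#' Extract Gaussian peaks from a flattened spectrum
#'
#' Greedy fitting of the periodic part of the spectral model: the largest
#' residual maximum is fitted with a Gaussian (nonlinear least squares),
#' the fitted bump subtracted, and the procedure repeated up to
#' `max_peaks` times. When two residual maxima tie, the lower frequency is
#' taken first. Peaks with fitted amplitude below `min_amplitude` are
#' discarded. An empty peak set is a valid outcome.
#'
#' @param spectrum A `power_spectrum`.
#' @param aperiodic An `aperiodic_fit` fitted on the same spectrum/channel.
#' @param max_peaks Maximum number of peaks (default 4).
#' @param min_amplitude Detection threshold in power units (default: 2x the
#'   robust scale of the flattened spectrum).
#' @param sd_bounds Allowed Gaussian bandwidth range in Hz.
#' @return An object of class `peak_set`: `peaks` (list of
#'   [gaussian_peak()], sorted by centre), `flattened` (freqs/power after
#'   aperiodic subtraction, floored at 0), `channel`.
#' @export
extract_peaks <- function(spectrum, aperiodic, max_peaks = 4L,
                          min_amplitude = NULL, sd_bounds = c(0.25, 4)) {
  flat0 <- flatten_spectrum(spectrum, aperiodic, floor_at_zero = FALSE)
  f <- flat0$freqs
  resid <- flat0$power
  if (is.null(min_amplitude)) {
    min_amplitude <- max(2 * mad(resid, center = 0), 1e-12)
  }

  peaks <- list()
  for (i in seq_len(max_peaks)) {
    idx <- which.max(resid)      # ties resolve to the lowest frequency
    if (resid[idx] < min_amplitude) break
    start <- list(a = resid[idx], mu = f[idx], s = 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ a * exp(-(fg - mu)^2 / (2 * s^2)),
        data = list(r = resid, fg = f),
        start = start,
        lower = c(0, min(f), sd_bounds[1]),
        upper = c(Inf, max(f), sd_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) break
    cf <- coef(fit)
    if (cf[["a"]] < min_amplitude) break
    pk <- gaussian_peak(cf[["mu"]], cf[["a"]], cf[["s"]])
    peaks[[length(peaks) + 1L]] <- pk
    resid <- resid - pk$amplitude *
      exp(-(f - pk$center_freq)^2 / (2 * pk$bandwidth_sd^2))
  }

  if (length(peaks) > 1L) {
    peaks <- peaks[order(vapply(peaks, `[[`, numeric(1), "center_freq"))]
  }
  structure(
    list(peaks = peaks,
         flattened = list(freqs = f, power = pmax(flat0$power, 0)),
         channel = aperiodic$channel),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s)\n", length(x$peaks)))
  for (p in x$peaks) {
    cat(sprintf("  %.3f Hz  amp %.3g  sd %.3g Hz\n",
                p$center_freq, p$amplitude, p$bandwidth_sd))
  }
  invisible(x)
}

#' Largest peak centre within a band
#'
#' @param peakset A `peak_set`.
#' @param band Numeric `c(lo, hi)` in Hz.
#' @return Centre frequency in Hz of the highest-amplitude peak inside the
#'   band, or `NA_real_` when none.
#' @export
peak_in_band <- function(peakset, band = c(7, 13)) {
  stopifnot(inherits(peakset, "peak_set"))
  cand <- Filter(function(p) {
    p$center_freq >= band[1] && p$center_freq <= band[2]
  }, peakset$peaks)
  if (length(cand) == 0L) return(NA_real_)
  amps <- vapply(cand, `[[`, numeric(1), "amplitude")
  cand[[which.max(amps)]]$center_freq
}
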