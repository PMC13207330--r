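#' Gaussian spectral peak
#'
#' One periodic (oscillatory) component of the parametric power-spectrum
#' model: a Gaussian bump of amplitude `amplitude` (power units) centred at
#' `center_freq` with standard-deviation bandwidth `bandwidth_sd`.
#'
#' @param center_freq Peak centre in Hz; must be positive.
#' @param amplitude Peak amplitude in power units; must be non-negative.
#' @param bandwidth_sd Gaussian standard deviation in Hz; must be positive.
#' @return An object of class `gaussian_peak`.
#' @examples
#' gaussian_peak(10, 1.5, 0.8)
#' @export
gaussian_peak <- function(center_freq, amplitude, bandwidth_sd) {
  stopifnot(is.numeric(center_freq), length(center_freq) == 1L, center_freq > 0)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, amplitude >= 0)
  stopifnot(is.numeric(bandwidth_sd), length(bandwidth_sd) == 1L, bandwidth_sd > 0)
  structure(
    list(center_freq = center_freq, amplitude = amplitude,
         bandwidth_sd = bandwidth_sd),
    class = "gaussian_peak"
  )
}

#' Parametric power-spectrum model
#'
#' The generative spectral model used throughout the package:
#' \deqn{P(f) = L + k f^{-x} + \sum_i a_i \exp\left(-\frac{(f-f_i)^2}{2\sigma_i^2}\right)}
#' where `L` is an additive white-noise floor, `k` the aperiodic offset,
#' `x` the aperiodic (1/f) exponent, and each Gaussian term a periodic
#' oscillation (e.g. the alpha peak).
#'
#' @param noise_floor Non-negative white-noise floor `L` (power units).
#' @param aperiodic_offset Non-negative aperiodic offset `k` (power units).
#' @param aperiodic_exponent Non-negative 1/f exponent `x`.
#' @param peaks List of [gaussian_peak()] objects; stored sorted by
#'   centre frequency.
#' @return An object of class `spectral_model`.
#' @seealso [evaluate_model_psd()], [synthesize_recording()]
#' @examples
#' m <- spectral_model(0.05, 5, 1.2, list(gaussian_peak(10, 1.5, 0.8)))
#' evaluate_model_psd(m, c(5, 10, 20))
#' @export
spectral_model <- function(noise_floor = 0, aperiodic_offset = 0,
                           aperiodic_exponent = 0, peaks = list()) {
  stopifnot(noise_floor >= 0, aperiodic_offset >= 0, aperiodic_exponent >= 0)
  stopifnot(is.list(peaks))
  for (p in peaks) {
    if (!inherits(p, "gaussian_peak")) {
      stop("all elements of `peaks` must be gaussian_peak objects")
    }
  }
  if (length(peaks) > 1L) {
    peaks <- peaks[order(vapply(peaks, `[[`, numeric(1), "center_freq"))]
  }
  structure(
    list(noise_floor = noise_floor, aperiodic_offset = aperiodic_offset,
         aperiodic_exponent = aperiodic_exponent, peaks = peaks),
    class = "spectral_model"
  )
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf(
    "<spectral_model> floor L=%.4g, offset k=%.4g, exponent x=%.3g, %d peak(s)\n",
    x$noise_floor, x$aperiodic_offset, x$aperiodic_exponent, length(x$peaks)))
  for (p in x$peaks) {
    cat(sprintf("  peak: %.3g Hz, amplitude %.3g, sd %.3g Hz\n",
                p$center_freq, p$amplitude, p$bandwidth_sd))
  }
  invisible(x)
}

#' Evaluate the model power spectral density
#'
#' Evaluates `L + k f^(-x) + sum_i a_i exp(-(f - f_i)^2 / (2 sigma_i^2))`
#' pointwise on a frequency grid.
#'
#' @param model A [spectral_model()].
#' @param freqs Numeric vector of frequencies in Hz; all must be positive
#'   (the aperiodic term is undefined at 0).
#' @return Numeric vector of power values, one per frequency.
#' @examples
#' m <- spectral_model(0, 1, 1, list(gaussian_peak(10, 2, 1)))
#' evaluate_model_psd(m, 10)  # 0.1 + 2 = 2.1
#' @export
evaluate_model_psd <- function(model, freqs) {
  stopifnot(inherits(model, "spectral_model"), is.numeric(freqs))
  if (any(freqs <= 0)) {
    stop("all frequencies must be > 0: the aperiodic term f^(-x) is undefined at 0")
  }
  p <- model$noise_floor + model$aperiodic_offset * freqs^(-model$aperiodic_exponent)
  for (pk in model$peaks) {
    p <- p + pk$amplitude *
      exp(-(freqs - pk$center_freq)^2 / (2 * pk$bandwidth_sd^2))
  }
  p
}

#' MCI-like and healthy default spectral models
#'
#' Convenience constructors for the two phenotypes the simulator contrasts:
#' a slowed-alpha, theta-elevated profile (typical of mild cognitive
#' impairment) and a healthy 10 Hz-alpha profile.
#'
#' @param iapf Alpha peak centre in Hz.
#' @param alpha_amplitude,theta_amplitude Peak amplitudes (power units).
#' @param exponent Aperiodic 1/f exponent.
#' @param offset Aperiodic offset `k`.
#' @param noise_floor White-noise floor `L`.
#' @param alpha_sd,theta_sd Peak bandwidths in Hz.
#' @return A [spectral_model()].
#' @export
mci_model <- function(iapf = 9.2, alpha_amplitude = 0.8, theta_amplitude = 0.6,
                      exponent = 1.5, offset = 5, noise_floor = 0.02,
                      alpha_sd = 0.8, theta_sd = 1.0) {
  spectral_model(noise_floor, offset, exponent, list(
    gaussian_peak(6, theta_amplitude, theta_sd),
    gaussian_peak(iapf, alpha_amplitude, alpha_sd)
  ))
}

#' @rdname mci_model
#' @export
healthy_model <- function(iapf = 10.25, alpha_amplitude = 1.5,
                          theta_amplitude = 0.25, exponent = 1.1, offset = 5,
                          noise_floor = 0.02, alpha_sd = 0.8, theta_sd = 1.0) {
  spectral_model(noise_floor, offset, exponent, list(
    gaussian_peak(6, theta_amplitude, theta_sd),
    gaussian_peak(iapf, alpha_amplitude, alpha_sd)
  ))
}
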