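#' Virtual neurofeedback subject
#'
#' The responsive "digital subject" closing the simulated loop. Its state
#' is the small set of spectral parameters the training is meant to move:
#' the individual alpha peak frequency (i-APF), alpha and theta peak
#' amplitudes, and the aperiodic exponent. A rewarded epoch moves each
#' parameter toward its training target by `responsiveness x (target -
#' current)`; a non-rewarded epoch relaxes toward the subject's baseline at
#' one fifth of that rate. The i-APF never exceeds `iapf_ceiling`.
#'
#' @param iapf Starting alpha peak frequency in Hz, in (4, 14).
#' @param alpha_amplitude,theta_amplitude Starting peak amplitudes.
#' @param aperiodic_exponent Starting 1/f exponent.
#' @param responsiveness Learning rate per rewarded epoch (>= 0).
#' @param iapf_ceiling Hard upper bound on the i-APF in Hz; default
#'   `max(10.5, iapf)`.
#' @param target_iapf,target_alpha,target_theta,target_exponent Training
#'   targets (the normative direction).
#' @return An object of class `virtual_subject`.
#' @seealso [subject_step()], [draw_mci_subject()]
#' @export
virtual_subject <- function(iapf = 9.2, alpha_amplitude = 0.8,
                            theta_amplitude = 0.6, aperiodic_exponent = 1.5,
                            responsiveness = 0.002, iapf_ceiling = NULL,
                            target_iapf = 10.5, target_alpha = 1.5,
                            target_theta = 0.25, target_exponent = 1.1) {
  if (is.null(iapf_ceiling)) iapf_ceiling <- max(10.5, iapf)
  stopifnot(iapf > 4, iapf < 14, responsiveness >= 0, iapf <= iapf_ceiling)
  structure(
    list(iapf = iapf, alpha_amplitude = alpha_amplitude,
         theta_amplitude = theta_amplitude,
         aperiodic_exponent = aperiodic_exponent,
         responsiveness = responsiveness, iapf_ceiling = iapf_ceiling,
         target = list(iapf = min(target_iapf, iapf_ceiling),
                       alpha_amplitude = target_alpha,
                       theta_amplitude = target_theta,
                       aperiodic_exponent = target_exponent),
         baseline = list(iapf = iapf, alpha_amplitude = alpha_amplitude,
                         theta_amplitude = theta_amplitude,
                         aperiodic_exponent = aperiodic_exponent)),
    class = "virtual_subject"
  )
}

#' Draw a subject from the MCI prior
#'
#' i-APF ~ Normal(9.2, 1.2^2) truncated to (7, 12) Hz, the prior used for
#' the 76+ MCI cohort; other parameters at the MCI defaults.
#'
#' @param seed Integer seed.
#' @param responsiveness Learning rate per rewarded epoch.
#' @param ... Passed to [virtual_subject()].
#' @return A `virtual_subject`.
#' @export
draw_mci_subject <- function(seed, responsiveness = 0.002, ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  repeat {
    iapf <- rnorm(1, mean = 9.2, sd = 1.2)
    if (iapf > 7 && iapf < 12) break
  }
  virtual_subject(iapf = iapf, responsiveness = responsiveness, ...)
}

#' Advance the virtual subject by one epoch
#'
#' Deterministic update given the state and the reward flag (see
#' [virtual_subject()] for the rule).
#'
#' @param state A `virtual_subject`.
#' @param rewarded Logical flag for the epoch.
#' @return The updated `virtual_subject`.
#' @export
subject_step <- function(state, rewarded) {
  stopifnot(inherits(state, "virtual_subject"), is.logical(rewarded),
            length(rewarded) == 1L, !is.na(rewarded))
  fields <- c("iapf", "alpha_amplitude", "theta_amplitude",
              "aperiodic_exponent")
  if (rewarded) {
    rate <- state$responsiveness
    ref <- state$target
  } else {
    rate <- state$responsiveness / 5
    ref <- state$baseline
  }
  for (f in fields) {
    state[[f]] <- state[[f]] + rate * (ref[[f]] - state[[f]])
  }
  state$iapf <- min(state$iapf, state$iapf_ceiling)
  state
}

#' Spectral model of the subject's current state
#'
#' @param state A `virtual_subject`.
#' @param offset,noise_floor Aperiodic offset and noise floor (fixed; the
#'   trained parameters are the peaks and the exponent).
#' @param alpha_sd,theta_sd Peak bandwidths in Hz.
#' @return A [spectral_model()].
#' @export
subject_model <- function(state, offset = 5, noise_floor = 0.02,
                          alpha_sd = 0.8, theta_sd = 1.0) {
  stopifnot(inherits(state, "virtual_subject"))
  spectral_model(noise_floor, offset, state$aperiodic_exponent, list(
    gaussian_peak(6, state$theta_amplitude, theta_sd),
    gaussian_peak(state$iapf, state$alpha_amplitude, alpha_sd)
  ))
}
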