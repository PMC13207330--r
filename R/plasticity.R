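#' BCM plasticity state
#'
#' One synapse under the Bienenstock-Cooper-Munro rule with the quadratic
#' nonlinearity `phi(y, theta_m) = phi_gain * y * (y - theta_m)`:
#' depression for `0 < y < theta_m`, zero at `y = theta_m`, potentiation
#' above.
#'
#' @param weight Synaptic weight.
#' @param presynaptic_input Presynaptic drive `x >= 0`.
#' @param postsynaptic_activity Postsynaptic activity `y`.
#' @param sliding_threshold Threshold `theta_m > 0`.
#' @param phi_gain Slope of the nonlinearity (default 1).
#' @param y0 Scale of the sliding-threshold rule (default 1).
#' @return An object of class `bcm_state`.
#' @export
bcm_state <- function(weight = 0, presynaptic_input = 1,
                      postsynaptic_activity = 0, sliding_threshold = 1,
                      phi_gain = 1, y0 = 1) {
  stopifnot(presynaptic_input >= 0, sliding_threshold > 0, y0 > 0)
  structure(
    list(weight = weight, presynaptic_input = presynaptic_input,
         postsynaptic_activity = postsynaptic_activity,
         sliding_threshold = sliding_threshold, phi_gain = phi_gain,
         y0 = y0),
    class = "bcm_state"
  )
}

#' BCM weight derivative
#'
#' `dw/dt = phi(y, theta_m) * x` with the quadratic BCM nonlinearity:
#' negative (LTD) for `0 < y < theta_m`, zero at `y = theta_m`, positive
#' (LTP) for `y > theta_m`.
#'
#' @param state A `bcm_state`.
#' @return Scalar `dw/dt`.
#' @export
bcm_dw <- function(state) {
  stopifnot(inherits(state, "bcm_state"))
  y <- state$postsynaptic_activity
  state$phi_gain * y * (y - state$sliding_threshold) * state$presynaptic_input
}

#' Sliding-threshold update
#'
#' The standard metaplasticity rule `theta_m <- mean(y^2) / y0` over a
#' window of recent postsynaptic activity. Constant activity at `y0` is a
#' fixed point; the rule is quadratically homogeneous in `y`.
#'
#' @param state A `bcm_state`.
#' @param recent_y Non-empty numeric window of recent activity.
#' @return The state with `sliding_threshold` updated.
#' @export
bcm_threshold_update <- function(state, recent_y) {
  stopifnot(inherits(state, "bcm_state"))
  if (length(recent_y) == 0L) stop("recent_y window must be non-empty")
  state$sliding_threshold <- mean(recent_y^2) / state$y0
  state
}

#' Homeostatic synaptic scaling state
#'
#' @param global_factor Multiplicative scaling factor `G > 0`.
#' @param firing_rate Current rate `R`.
#' @param target_rate Homeostatic set point `R_target`.
#' @param rate_constant Scaling rate `gamma > 0`.
#' @return An object of class `scaling_state`.
#' @export
scaling_state <- function(global_factor = 1, firing_rate = 0,
                          target_rate = 5, rate_constant = 0.1) {
  stopifnot(global_factor > 0, rate_constant > 0)
  structure(
    list(global_factor = global_factor, firing_rate = firing_rate,
         target_rate = target_rate, rate_constant = rate_constant),
    class = "scaling_state"
  )
}

#' Synaptic scaling derivative
#'
#' `dG/dt = gamma * (R_target - R)`: upscaling when activity is below
#' target, downscaling above.
#'
#' @param state A `scaling_state`.
#' @return Scalar `dG/dt`.
#' @export
scaling_dG <- function(state) {
  stopifnot(inherits(state, "scaling_state"))
  state$rate_constant * (state$target_rate - state$firing_rate)
}

#' STDP kernel
#'
#' Exponential spike-timing-dependent plasticity kernel with a hard
#' pairing window: `W(dt) = A_plus * exp(-dt/tau)` for `0 < dt < cutoff`,
#' `-A_minus * exp(dt/tau)` for `-cutoff < dt < 0`, and 0 for
#' `|dt| >= cutoff` or `dt = 0`. Outside the (default 40 ms) window the
#' reinforcement fails.
#'
#' @param potentiation_amp `A_plus >= 0`.
#' @param depression_amp `A_minus >= 0`.
#' @param time_constant `tau` in ms.
#' @param cutoff_window Hard window in ms (default 40).
#' @return An object of class `stdp_kernel`.
#' @export
stdp_kernel <- function(potentiation_amp = 1, depression_amp = 1,
                        time_constant = 20, cutoff_window = 40) {
  stopifnot(potentiation_amp >= 0, depression_amp >= 0,
            time_constant > 0, cutoff_window > 0)
  structure(
    list(potentiation_amp = potentiation_amp,
         depression_amp = depression_amp,
         time_constant = time_constant, cutoff_window = cutoff_window),
    class = "stdp_kernel"
  )
}

#' STDP weight change over spike trains
#'
#' `Delta w = sum_pre sum_post W(t_post - t_pre)` with the kernel above.
#' Empty trains are valid (contribute 0); the sum is additive over
#' disjoint train segments.
#'
#' @param pre_spikes,post_spikes Sorted spike times in ms.
#' @param kernel An `stdp_kernel`.
#' @return Scalar weight change.
#' @export
stdp_dw <- function(pre_spikes, post_spikes, kernel = stdp_kernel()) {
  stopifnot(inherits(kernel, "stdp_kernel"))
  if (length(pre_spikes) == 0L || length(post_spikes) == 0L) return(0)
  dt <- outer(post_spikes, pre_spikes, "-")      # t_post - t_pre
  w <- numeric(length(dt))
  pos <- dt > 0 & dt < kernel$cutoff_window
  neg <- dt < 0 & dt > -kernel$cutoff_window
  w[pos] <- kernel$potentiation_amp * exp(-dt[pos] / kernel$time_constant)
  w[neg] <- -kernel$depression_amp * exp(dt[neg] / kernel$time_constant)
  sum(w)
}
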