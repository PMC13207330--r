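#' Adaptive Bayesian reward-threshold controller state
#'
#' Recursive belief over the feedback signal `y` (a positive power ratio or
#' band power) used to hold the rewarded-epoch fraction at a target
#' success probability `rho_star` - the "70% rule" at the clinical
#' operating point (85% optimum minus a 15% clinical safety offset; see
#' [operating_point()]).
#'
#' Two backends are provided:
#' \describe{
#'   \item{`conjugate`}{Normal-inverse-gamma belief on `log y` with
#'     exponential forgetting on the sufficient statistics; the reward
#'     threshold is the posterior-predictive (Student-t) quantile giving
#'     success probability `rho_star` under the configured direction.}
#'   \item{`empirical`}{Distribution-free tracker: the threshold is the
#'     empirical quantile of a sliding window of recent `y` values.}
#' }
#'
#' @param rho_star Target success probability in (0, 1), default 0.70.
#' @param direction `"suppress"` (success = `y < theta`, e.g. lowering a
#'   Theta/Alpha ratio) or `"enhance"` (success = `y > theta`).
#' @param backend `"conjugate"` or `"empirical"`.
#' @param mu0,kappa0,a0,b0 Normal-inverse-gamma prior on `log y` (vague by
#'   default).
#' @param forgetting Exponential discount on the sufficient statistics per
#'   update, in (0, 1]; 1 = no forgetting. Default 0.99 (effective memory
#'   of about 100 epochs) so the controller re-converges after
#'   distributional shifts.
#' @param window Sliding-window length for the empirical backend.
#' @param update_period Seconds between threshold updates (bookkeeping;
#'   default 1 s epochs).
#' @return An object of class `bdws_posterior`.
#' @export
bdws_posterior <- function(rho_star = 0.70,
                           direction = c("suppress", "enhance"),
                           backend = c("conjugate", "empirical"),
                           mu0 = 0, kappa0 = 0.01, a0 = 0.5, b0 = 0.5,
                           forgetting = 0.99, window = 300L,
                           update_period = 1) {
  direction <- match.arg(direction)
  backend <- match.arg(backend)
  stopifnot(rho_star > 0, rho_star < 1, forgetting > 0, forgetting <= 1)
  structure(
    list(rho_star = rho_star, rho_effective = rho_star,
         direction = direction, backend = backend,
         mu = mu0, kappa = kappa0, a = a0, b = b0,
         forgetting = forgetting,
         buffer = numeric(0), window = as.integer(window),
         theta = NA_real_, n_obs = 0L, n_rejected = 0L,
         update_period = update_period, gate_log = integer(0)),
    class = "bdws_posterior"
  )
}

#' @export
print.bdws_posterior <- function(x, ...) {
  cat(sprintf(
    "<bdws_posterior> %s backend, rho*=%.2f (effective %.2f), direction=%s, theta=%s, n=%d\n",
    x$backend, x$rho_star, x$rho_effective, x$direction,
    ifelse(is.na(x$theta), "unset", sprintf("%.4g", x$theta)), x$n_obs))
  invisible(x)
}

#' Recursive posterior update and threshold reset
#'
#' One step of the recursive Bayesian estimator: absorb the epoch's
#' feedback value `y_t`, then reset the reward threshold to the quantile of
#' the predictive distribution of `y` that yields success probability
#' `rho_effective` under the configured direction (suppress: the
#' `rho`-quantile; enhance: the `(1 - rho)`-quantile). Non-positive `y_t`
#' is rejected (logged; posterior unchanged).
#'
#' @param posterior A `bdws_posterior`.
#' @param y_t Positive feedback value for the epoch.
#' @return The updated `bdws_posterior` (with `theta` set).
#' @export
update_posterior <- function(posterior, y_t) {
  stopifnot(inherits(posterior, "bdws_posterior"))
  if (!is.finite(y_t) || y_t <= 0) {
    posterior$n_rejected <- posterior$n_rejected + 1L
    return(posterior)
  }
  p <- posterior
  if (p$backend == "conjugate") {
    x <- log(y_t)
    lam <- p$forgetting
    kappa <- lam * p$kappa
    a <- lam * p$a
    b <- lam * p$b
    mu_n <- (kappa * p$mu + x) / (kappa + 1)
    p$b <- b + kappa * (x - p$mu)^2 / (2 * (kappa + 1))
    p$mu <- mu_n
    p$kappa <- kappa + 1
    p$a <- a + 0.5
    # Posterior predictive of log y: Student-t.
    df <- 2 * p$a
    scale <- sqrt(p$b * (p$kappa + 1) / (p$a * p$kappa))
    q <- if (p$direction == "suppress") p$rho_effective else 1 - p$rho_effective
    p$theta <- exp(p$mu + scale * qt(q, df))
  } else {
    p$buffer <- c(p$buffer, y_t)
    if (length(p$buffer) > p$window) {
      p$buffer <- p$buffer[(length(p$buffer) - p$window + 1L):length(p$buffer)]
    }
    q <- if (p$direction == "suppress") p$rho_effective else 1 - p$rho_effective
    p$theta <- unname(quantile(p$buffer, probs = q, type = 7))
  }
  p$n_obs <- p$n_obs + 1L
  p
}

#' Reward decision
#'
#' Suppress direction rewards `y < theta`; enhance rewards `y > theta`;
#' equality never rewards (documented tie rule).
#'
#' @param y Feedback value.
#' @param theta Current threshold.
#' @param direction `"suppress"` or `"enhance"`.
#' @return Logical.
#' @export
reward_decision <- function(y, theta, direction = c("suppress", "enhance")) {
  direction <- match.arg(direction)
  if (is.na(theta)) return(FALSE)
  if (direction == "suppress") y < theta else y > theta
}

#' Trailing success rate
#'
#' @param rewarded Logical vector of per-epoch reward outcomes (or a
#'   data.frame with a `rewarded` column).
#' @param window Number of trailing epochs; must not exceed the available
#'   epochs.
#' @return Fraction rewarded over the trailing window.
#' @export
success_rate <- function(rewarded, window = length(rewarded)) {
  if (is.data.frame(rewarded)) rewarded <- rewarded$rewarded
  if (window < 1 || window > length(rewarded)) {
    stop("window must be between 1 and the number of events")
  }
  mean(tail(rewarded, window))
}

#' Information gain (binary entropy) of a success probability
#'
#' `H(p) = -p log2 p - (1 - p) log2 (1 - p)` in bits, with the limits at 0
#' and 1 defined as 0. Maximal (1 bit) at p = 0.5; H(0.70) > H(0.85), the
#' information-theoretic argument for keeping training challenging.
#'
#' @param p Probability in `[0, 1]` (vectorized).
#' @return Entropy in bits.
#' @export
information_gain <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Clinical operating point
#'
#' The target success rate as an optimum minus a clinical safety offset:
#' the default 0.85 - 0.15 = 0.70 ("70% rule" for clinical populations);
#' offset 0 recovers the healthy-population 85% rule.
#'
#' @param base Optimal success rate (default 0.85).
#' @param clinical_offset Safety offset subtracted for impaired
#'   populations (default 0.15).
#' @return `rho_star = base - clinical_offset`, validated to lie in (0, 1).
#' @export
operating_point <- function(base = 0.85, clinical_offset = 0.15) {
  rho <- base - clinical_offset
  if (!(rho > 0 && rho < 1)) {
    stop("operating point must lie strictly between 0 and 1")
  }
  rho
}

#' Assign a training tier from the BDWS score
#'
#' The BDWS score is the posterior-mean success percentage over the
#' assessment window. Tiers: High-Performance for scores in `[85, 100]`
#' (one 20-30 min continuous block, high-reward schedule), Medium for
#' `[75, 85)` (20 min block), High-Intensity Training (HIT) for `[0, 75)`
#' (15 min total as 5 min active / 5 min rest / 5 min active). The
#' tier bounds overlap at 75 and 85; boundaries resolve upward
#' (85 -> High, 75 -> Medium).
#'
#' @param bdws_score Percentage in `[0, 100]`.
#' @return An object of class `tier_assignment`: `tier`, `bdws_score`,
#'   `block_plan` (data.frame of `phase`, `minutes`).
#' @export
assign_tier <- function(bdws_score) {
  if (!is.finite(bdws_score) || bdws_score < 0 || bdws_score > 100) {
    stop("bdws_score must lie in [0, 100]")
  }
  if (bdws_score >= 85) {
    tier <- "HighPerformance"
    plan <- data.frame(phase = "active", minutes = 25,
                       reward_schedule = "high", stringsAsFactors = FALSE)
  } else if (bdws_score >= 75) {
    tier <- "MediumPerformance"
    plan <- data.frame(phase = "active", minutes = 20,
                       reward_schedule = "medium", stringsAsFactors = FALSE)
  } else {
    tier <- "HIT"
    plan <- data.frame(phase = c("active", "rest", "active"),
                       minutes = c(5, 5, 5),
                       reward_schedule = c("low", "rest", "low"),
                       stringsAsFactors = FALSE)
  }
  structure(list(tier = tier, bdws_score = bdws_score, block_plan = plan),
            class = "tier_assignment")
}

#' Heart-rate-variability state
#'
#' @param current Current HRV metric (e.g. RMSSD in ms).
#' @param baseline Subject baseline (> 0).
#' @param drop_fraction Fractional drop below baseline that triggers the
#'   gate (default 0.2).
#' @return An object of class `hrv_state`.
#' @export
hrv_state <- function(current, baseline, drop_fraction = 0.2) {
  stopifnot(baseline > 0, drop_fraction >= 0)
  structure(list(current = current, baseline = baseline,
                 drop_fraction = drop_fraction),
            class = "hrv_state")
}

#' HRV cross-looping gate
#'
#' Autonomic safety valve: when the HRV metric drops below
#' `(1 - drop_fraction) x baseline`, the controller's effective success
#' target is raised by `ease_step` (easier training, more rewards), capped
#' at 0.9. Gate activations are logged on the posterior.
#'
#' @param hrv An `hrv_state`.
#' @param posterior A `bdws_posterior`.
#' @param ease_step Increment applied to the effective target (default
#'   0.05).
#' @return The (possibly eased) `bdws_posterior`.
#' @export
hrv_gate <- function(hrv, posterior, ease_step = 0.05) {
  stopifnot(inherits(hrv, "hrv_state"), inherits(posterior, "bdws_posterior"),
            ease_step >= 0)
  if (hrv$current < (1 - hrv$drop_fraction) * hrv$baseline) {
    posterior$rho_effective <- min(0.9, posterior$rho_effective + ease_step)
    posterior$gate_log <- c(posterior$gate_log, posterior$n_obs)
  }
  posterior
}

#' Static-threshold baseline controller
#'
#' A non-adaptive reference controller (fixed threshold from a calibration
#' sample) used to demonstrate why a static threshold loses the set point
#' after distributional drift.
#'
#' @param calibration Numeric vector of calibration `y` values.
#' @param rho_star Target success probability.
#' @param direction As in [bdws_posterior()].
#' @return A list with the fixed `theta` and `direction`.
#' @export
static_threshold <- function(calibration, rho_star = 0.70,
                             direction = c("suppress", "enhance")) {
  direction <- match.arg(direction)
  q <- if (direction == "suppress") rho_star else 1 - rho_star
  list(theta = unname(quantile(calibration, q, type = 7)),
       direction = direction)
}
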