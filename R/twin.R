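#' Synthetic 76-region connectome
#'
#' A deterministic synthetic whole-brain coupling matrix standing in for a
#' Desikan-Killiany-style parcellation: regions are placed on two
#' mirrored hemispheric shells and coupled with exponentially
#' distance-dependent weights plus weak homotopic (mirror-region) links.
#' Synthetic - not derived from any atlas or subject data.
#'
#' @param n_regions Number of regions (default 76).
#' @param seed Seed for the small random weight jitter.
#' @return Symmetric non-negative `n_regions x n_regions` matrix with zero
#'   diagonal.
#' @export
dk_connectome <- function(n_regions = 76L, seed = 42L) {
  stopifnot(n_regions >= 2L)
  half <- ceiling(n_regions / 2)
  dirs <- fibonacci_sphere(half)
  left <- cbind(-abs(dirs[, 1]) - 0.1, dirs[, 2], dirs[, 3])
  right <- cbind(abs(dirs[, 1]) + 0.1, dirs[, 2], dirs[, 3])
  pos <- rbind(left, right)[seq_len(n_regions), , drop = FALSE]
  d <- as.matrix(stats::dist(pos))
  C <- exp(-d / 0.8)
  # Homotopic links between mirrored regions.
  for (i in seq_len(min(half, n_regions - half))) {
    C[i, half + i] <- C[i, half + i] + 0.5
    C[half + i, i] <- C[i, half + i]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  jitter <- matrix(runif(n_regions^2, 0.9, 1.1), n_regions)
  jitter <- (jitter + t(jitter)) / 2
  C <- C * jitter
  diag(C) <- 0
  C <- C / max(C)
  dimnames(C) <- NULL
  C
}

#' Digital-twin configuration
#'
#' Defaults follow the reference twin configuration: 76 coupled
#' regions, global coupling strength `G = 0.015`, sigmoid gain shape
#' `d = 0.3` (a Hill-type gain coefficient, implemented as the slope scale
#' of the logistic transfer function), 2000 ms simulated at 1 ms Euler
#' steps.
#'
#' @param n_regions Number of regions.
#' @param connectome Coupling matrix (default [dk_connectome()]).
#' @param coupling_strength Global coupling `G`.
#' @param hill_coefficient Sigmoid slope scale `d`.
#' @param duration Simulation length in ms.
#' @param tau Node time constant in ms.
#' @param noise_sd Per-step state noise SD.
#' @param input Per-region constant drive (scalar or vector).
#' @param seed Seed for initial conditions and noise.
#' @return An object of class `twin_config`.
#' @export
twin_config <- function(n_regions = 76L, connectome = NULL,
                        coupling_strength = 0.015, hill_coefficient = 0.3,
                        duration = 2000, tau = 10, noise_sd = 0.001,
                        input = 0, seed = 1L) {
  if (is.null(connectome)) connectome <- dk_connectome(n_regions)
  connectome <- as.matrix(connectome)
  stopifnot(nrow(connectome) == n_regions, ncol(connectome) == n_regions)
  if (any(connectome < 0)) stop("connectome must be non-negative")
  if (any(abs(diag(connectome)) > 1e-12)) stop("connectome needs zero diagonal")
  stopifnot(coupling_strength >= 0, hill_coefficient > 0, duration >= 10,
            tau > 0, noise_sd >= 0)
  structure(
    list(n_regions = n_regions, connectome = connectome,
         coupling_strength = coupling_strength,
         hill_coefficient = hill_coefficient, duration = duration,
         tau = tau, noise_sd = noise_sd,
         input = rep_len(input, n_regions), seed = seed),
    class = "twin_config"
  )
}

#' Simulate the digital-twin rate network
#'
#' Euler integration (1 ms steps) of
#' `tau dr_i/dt = -r_i + S(G sum_j C_ij r_j + I_i) + noise`,
#' with the logistic transfer `S(u) = 1 / (1 + exp(-(u - 0.5)/d))`. With
#' zero coupling and input every region decays to the uncoupled fixed
#' point `r* = S(0)`.
#'
#' @param config A `twin_config`.
#' @param drift_tol Settling criterion: mean absolute per-ms drift over
#'   the final 10% of the run must stay below this (default 1e-3).
#' @return An object of class `twin_result`: `trajectories`
#'   (time x region), `settled`, `diverged`, `per_region_variance`
#'   (post-transient), `mean_synchrony` (mean pairwise correlation),
#'   `final_state`, `config`.
#' @export
twin_simulate <- function(config, drift_tol = 1e-3) {
  stopifnot(inherits(config, "twin_config"))
  n <- config$n_regions
  steps <- round(config$duration)          # 1 ms steps
  d <- config$hill_coefficient
  S <- function(u) 1 / (1 + exp(-(u - 0.5) / d))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(config$seed))
  r <- runif(n, 0, 0.2)
  traj <- matrix(NA_real_, steps, n)
  GC <- config$coupling_strength * config$connectome
  diverged <- FALSE
  for (t in seq_len(steps)) {
    drive <- drop(GC %*% r) + config$input
    noise <- if (config$noise_sd > 0) rnorm(n, sd = config$noise_sd) else 0
    r <- r + (-r + S(drive)) / config$tau + noise
    if (!all(is.finite(r)) || any(abs(r) > 1e6)) {
      diverged <- TRUE
      traj[t, ] <- r
      break
    }
    traj[t, ] <- r
  }

  tail_start <- max(1L, floor(steps * 0.9))
  tail_traj <- traj[tail_start:steps, , drop = FALSE]
  drift <- mean(abs(diff(tail_traj)))
  settled <- !diverged && is.finite(drift) && drift < drift_tol

  post <- traj[max(1L, floor(steps * 0.25)):steps, , drop = FALSE]
  per_region_variance <- apply(post, 2, var)
  sync <- NA_real_
  if (!diverged && all(per_region_variance > 0)) {
    cm <- cor(post)
    sync <- mean(cm[upper.tri(cm)])
  }

  structure(
    list(trajectories = traj, settled = settled, diverged = diverged,
         per_region_variance = per_region_variance, mean_synchrony = sync,
         drift = drift, final_state = r, config = config),
    class = "twin_result"
  )
}

#' @export
print.twin_result <- function(x, ...) {
  cat(sprintf(
    "<twin_result> %d regions, %d ms: settled=%s, diverged=%s, drift=%.2g\n",
    x$config$n_regions, nrow(x$trajectories), x$settled, x$diverged, x$drift))
  invisible(x)
}
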