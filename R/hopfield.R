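#' Hopfield network
#'
#' Symmetric binary attractor network: `weights` (zero diagonal), `states`
#' in {-1, +1}, per-unit `thresholds`. Attractor stabilization models the
#' therapeutic deepening of healthy activity patterns.
#'
#' @param weights Symmetric numeric matrix with zero diagonal.
#' @param states Vector in {-1, +1}.
#' @param thresholds Per-unit thresholds (default 0).
#' @return An object of class `hopfield_net`.
#' @export
hopfield_net <- function(weights, states, thresholds = rep(0, length(states))) {
  weights <- as.matrix(weights)
  if (!isSymmetric(unname(weights), tol = 1e-10)) {
    stop("Hopfield weights must be symmetric")
  }
  if (any(abs(diag(weights)) > 1e-12)) stop("Hopfield weights need zero diagonal")
  if (!all(states %in% c(-1, 1))) stop("states must be -1 or +1")
  stopifnot(length(states) == nrow(weights),
            length(thresholds) == length(states))
  structure(list(weights = weights, states = as.numeric(states),
                 thresholds = as.numeric(thresholds)),
            class = "hopfield_net")
}

#' Hopfield energy
#'
#' `E = -1/2 sum_ij w_ij s_i s_j + sum_i theta_i s_i`. With zero
#' thresholds this equals the pairwise form `-sum_{i<j} w_ij s_i s_j`
#' (see [hopfield_energy_pairwise()]).
#'
#' @param net A `hopfield_net`.
#' @param states Optional state vector to evaluate instead of the stored
#'   one.
#' @return Scalar energy.
#' @export
hopfield_energy <- function(net, states = net$states) {
  stopifnot(inherits(net, "hopfield_net"))
  s <- as.numeric(states)
  -0.5 * drop(s %*% net$weights %*% s) + sum(net$thresholds * s)
}

#' Pairwise-sum form of the Hopfield energy
#'
#' `E = -sum_{i<j} w_ij s_i s_j` (no threshold term); identical to
#' [hopfield_energy()] when all thresholds are zero.
#'
#' @inheritParams hopfield_energy
#' @return Scalar energy.
#' @export
hopfield_energy_pairwise <- function(net, states = net$states) {
  stopifnot(inherits(net, "hopfield_net"))
  s <- as.numeric(states)
  w <- net$weights
  -sum(w[upper.tri(w)] * tcrossprod(s)[upper.tri(w)])
}

#' One asynchronous update sweep
#'
#' Units update one at a time in the given order:
#' `s_i <- sign(sum_j w_ij s_j - theta_i)` with `sign(0) -> +1`
#' (deterministic tie rule). The energy never increases.
#'
#' @param net A `hopfield_net`.
#' @param update_order Integer permutation of the units, or a seed (scalar)
#'   from which a permutation is drawn; default the natural order.
#' @return List with the updated `net` and logical `changed`.
#' @export
hopfield_step <- function(net, update_order = seq_along(net$states)) {
  stopifnot(inherits(net, "hopfield_net"))
  n <- length(net$states)
  if (length(update_order) == 1L && n > 1L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(update_order))
    update_order <- sample.int(n)
  }
  stopifnot(setequal(update_order, seq_len(n)))
  s <- net$states
  changed <- FALSE
  for (i in update_order) {
    h <- sum(net$weights[i, ] * s) - net$thresholds[i]
    new_si <- if (h >= 0) 1 else -1
    if (new_si != s[i]) changed <- TRUE
    s[i] <- new_si
  }
  net$states <- s
  list(net = net, changed = changed)
}

#' Run asynchronous dynamics to a fixed point
#'
#' Repeated sweeps until no unit changes (guaranteed to terminate: finite
#' state space and monotone energy).
#'
#' @param net A `hopfield_net`.
#' @param max_sweeps Safety bound on the number of sweeps.
#' @param update_order As in [hopfield_step()].
#' @return The converged `hopfield_net`.
#' @export
hopfield_run <- function(net, max_sweeps = 1000L,
                         update_order = seq_along(net$states)) {
  for (i in seq_len(max_sweeps)) {
    res <- hopfield_step(net, update_order)
    net <- res$net
    if (!res$changed) return(net)
  }
  stop("no fixed point within max_sweeps sweeps")
}

#' Hebbian storage of patterns
#'
#' `w_ij = (1/n) mean_p s_i^p s_j^p` with zero diagonal, `n` the number of
#' units (averaging over patterns, so storing a pattern together with its
#' negation gives the same weights as the pattern alone: the pairwise
#' products cancel the sign).
#'
#' @param patterns List of {-1, +1} vectors of common length.
#' @return Weight matrix.
#' @export
hebbian_store <- function(patterns) {
  stopifnot(is.list(patterns), length(patterns) >= 1L)
  n <- length(patterns[[1]])
  w <- matrix(0, n, n)
  for (p in patterns) {
    if (length(p) != n) stop("patterns must all have the same length")
    if (!all(p %in% c(-1, 1))) stop("patterns must be -1/+1 vectors")
    w <- w + tcrossprod(as.numeric(p)) / n
  }
  w <- w / length(patterns)
  diag(w) <- 0
  w
}

#' Basin-deepening reinforcement of a target pattern
#'
#' `w <- w + rate * (outer(target) - I)`: one Hebbian reinforcement of the
#' target attractor. Strictly lowers the target's energy and preserves
#' symmetry and the zero diagonal.
#'
#' @param net A `hopfield_net`.
#' @param target_pattern {-1, +1} vector.
#' @param rate Non-negative learning rate.
#' @return The reinforced `hopfield_net`.
#' @export
reinforce_weights <- function(net, target_pattern, rate) {
  stopifnot(inherits(net, "hopfield_net"), rate >= 0,
            length(target_pattern) == length(net$states),
            all(target_pattern %in% c(-1, 1)))
  dw <- rate * tcrossprod(as.numeric(target_pattern))
  diag(dw) <- 0
  net$weights <- net$weights + dw
  net
}

#' Enumerate fixed points and basins by brute force
#'
#' For small networks (n <= 16) enumerates all 2^n states, identifies the
#' fixed points of the asynchronous dynamics, and maps every state to the
#' fixed point it converges to under sequential sweeps (natural unit
#' order). Used as the independent oracle for the dynamics.
#'
#' @param net A `hopfield_net` (its stored state is ignored).
#' @return List: `fixed_points` (matrix, one row per fixed point) and
#'   `basin_of` (integer vector over all 2^n states, indexing rows of
#'   `fixed_points`).
#' @export
hopfield_enumerate <- function(net) {
  n <- length(net$states)
  if (n > 16L) stop("enumeration limited to n <= 16")
  n_states <- 2L^n
  all_states <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  is_fixed <- logical(n_states)
  for (k in seq_len(n_states)) {
    s <- all_states[k, ]
    h <- drop(net$weights %*% s) - net$thresholds
    is_fixed[k] <- all(ifelse(h >= 0, 1, -1) == s)
  }
  fp_idx <- which(is_fixed)
  fixed_points <- all_states[fp_idx, , drop = FALSE]
  key <- function(s) as.integer(sum((s > 0) * 2^(seq_len(n) - 1L)) + 1)
  fp_lookup <- integer(n_states)
  fp_lookup[vapply(fp_idx, function(k) key(all_states[k, ]), 1L)] <-
    seq_along(fp_idx)
  basin_of <- integer(n_states)
  for (k in seq_len(n_states)) {
    net$states <- all_states[k, ]
    conv <- hopfield_run(net)
    basin_of[k] <- fp_lookup[key(conv$states)]
  }
  list(fixed_points = fixed_points, basin_of = basin_of)
}
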