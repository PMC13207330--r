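test_that("Hopfield energy matches hand-enumerated cases and symmetries", {
  z <- hopfield_net(matrix(0, 3, 3), c(1, -1, 1))
  expect_equal(hopfield_energy(z), 0)

  w <- matrix(c(0, 1, 1, 0), 2)
  net <- hopfield_net(w, c(1, 1))
  expect_equal(hopfield_energy(net), -1.0)
  expect_equal(hopfield_energy_pairwise(net), -1.0)

  # s -> -s symmetry at zero thresholds
  expect_equal(hopfield_energy(net, c(-1, -1)), hopfield_energy(net))

  # the two energy conventions coincide when thresholds vanish
  for (s in 1:5) {
    n <- 6
    net2 <- random_hopfield(n, seed = 100 + s, threshold_sd = 0)
    st <- net2$states
    expect_equal(hopfield_energy(net2, st), hopfield_energy_pairwise(net2, st))
  }

  expect_error(hopfield_net(matrix(c(0, 1, 0, 0), 2), c(1, 1)), "symmetric")
  expect_error(hopfield_net(diag(2), c(1, 1)), "zero diagonal")
})

test_that("asynchronous updates never increase the energy", {
  for (s in 1:50) {
    net <- random_hopfield(sample(3:10, 1), seed = 200 + s)
    for (k in 1:5) {
      e0 <- hopfield_energy(net)
      res <- hopfield_step(net, update_order = s + k)
      expect_lte(hopfield_energy(res$net), e0 + 1e-12)
      net <- res$net
    }
  }
})

test_that("stored patterns are fixed points; nearby states fall in", {
  pat <- c(1, -1, 1, 1, -1)
  w <- hebbian_store(list(pat))
  net <- hopfield_net(w, pat)
  res <- hopfield_step(net)
  expect_false(res$changed)

  # start at Hamming distance 1: converge back to the pattern
  for (flip in 1:5) {
    start <- pat; start[flip] <- -start[flip]
    conv <- hopfield_run(hopfield_net(w, start))
    expect_true(all(conv$states == pat) || all(conv$states == -pat))
  }
})

test_that("Hebbian storage follows the outer-product rule", {
  w <- hebbian_store(list(rep(1, 4)))
  expect_equal(w[upper.tri(w)], rep(1 / 4, 6))
  expect_equal(diag(w), rep(0, 4))

  pat <- c(1, -1, 1, -1)
  expect_equal(hebbian_store(list(pat, -pat)), hebbian_store(list(pat)))
  expect_error(hebbian_store(list(c(1, -1), c(1, -1, 1))), "same length")

  # two orthogonal patterns are energy minima over all 16 states
  p1 <- c(1, 1, -1, -1); p2 <- c(1, -1, 1, -1)
  w2 <- hebbian_store(list(p1, p2))
  net <- hopfield_net(w2, p1)
  all_states <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  energies <- apply(all_states, 1, function(s) hopfield_energy(net, s))
  e_stored <- hopfield_energy(net, p1)
  expect_equal(hopfield_energy(net, p2), e_stored)
  expect_equal(min(energies), e_stored)
})

test_that("reinforcement deepens the target basin", {
  net <- random_hopfield(6, seed = 31)
  target <- c(1, -1, 1, -1, 1, 1)

  expect_identical(reinforce_weights(net, target, 0)$weights, net$weights)

  e0 <- hopfield_energy(net, target)
  net1 <- reinforce_weights(net, target, 0.2)
  expect_lt(hopfield_energy(net1, target), e0)
  expect_true(isSymmetric(net1$weights))
  expect_equal(diag(net1$weights), rep(0, 6))

  # basin size (brute force over 64 states) never shrinks under reinforcement
  basin_size <- function(nt) {
    enum <- hopfield_enumerate(nt)
    fp <- enum$fixed_points
    tgt_row <- which(apply(fp, 1, function(s) all(s == target)))
    if (length(tgt_row) == 0) return(0L)
    sum(enum$basin_of == tgt_row)
  }
  sizes <- c(basin_size(net), basin_size(net1),
             basin_size(reinforce_weights(net1, target, 0.2)))
  expect_true(all(diff(sizes) >= 0))
  expect_gt(sizes[3], 0)
})

test_that("dynamics and basins match brute-force enumeration (oracle)", {
  for (s in 1:100) {
    n <- 3 + (s %% 6)                    # sizes 3..8
    net <- random_hopfield(n, seed = 300 + s)
    enum <- hopfield_enumerate(net)
    expect_gt(nrow(enum$fixed_points), 0)
    # every enumerated fixed point is invariant under a sweep
    for (r in seq_len(nrow(enum$fixed_points))) {
      net$states <- enum$fixed_points[r, ]
      expect_false(hopfield_step(net)$changed)
    }
    # dynamics from 10 random starts land on the enumerated basin targets
    set.seed(400 + s)
    for (k in 1:10) {
      st <- sample(c(-1, 1), n, replace = TRUE)
      idx <- as.integer(sum((st > 0) * 2^(seq_len(n) - 1)) + 1)
      net$states <- st
      conv <- hopfield_run(net)
      expect_equal(unname(conv$states),
                   unname(enum$fixed_points[enum$basin_of[idx], ]))
    }
  }
})

test_that("BCM sign structure matches the plasticity window", {
  mk <- function(y, th, x = 1) bcm_state(presynaptic_input = x,
                                         postsynaptic_activity = y,
                                         sliding_threshold = th)
  expect_equal(bcm_dw(mk(1, 1)), 0)              # y = theta_m
  expect_gt(bcm_dw(mk(2, 1)), 0)                 # LTP above threshold
  expect_lt(bcm_dw(mk(0.5, 1)), 0)               # LTD below
  expect_equal(bcm_dw(mk(2, 1, x = 0)), 0)       # no presynaptic drive

  for (y in c(0.2, 0.8, 1, 1.5, 3)) {
    for (th in c(0.5, 1, 2)) {
      dw <- bcm_dw(mk(y, th))
      expect_equal(sign(dw), sign(y - th) * (y > 0))
    }
  }
})

test_that("the sliding threshold follows mean(y^2)/y0", {
  st <- bcm_state(y0 = 1)
  expect_equal(bcm_threshold_update(st, rep(1, 10))$sliding_threshold, 1)
  up <- bcm_threshold_update(st, c(1, 2, 3))
  up2 <- bcm_threshold_update(st, 2 * c(1, 2, 3))
  expect_equal(up2$sliding_threshold, 4 * up$sliding_threshold)
  expect_error(bcm_threshold_update(st, numeric(0)), "non-empty")

  # saturation guard: with the threshold sliding on y^2, the closed loop
  # y = w x settles where y = theta_m, i.e. y* = y0 (scalar fixed point)
  st2 <- bcm_state(y0 = 1, presynaptic_input = 1)
  w <- 1.3
  for (i in 1:2000) {
    y_now <- w * st2$presynaptic_input
    st2 <- bcm_threshold_update(st2, rep(y_now, 5))
    st2$postsynaptic_activity <- y_now
    w <- w + 0.02 * bcm_dw(st2)
  }
  expect_equal(w * st2$presynaptic_input, 1, tolerance = 1e-3)
  expect_lt(abs(bcm_dw(st2)), 1e-3)
})

test_that("synaptic scaling drives the rate to target", {
  expect_equal(scaling_dG(scaling_state(firing_rate = 5, target_rate = 5)), 0)
  expect_gt(scaling_dG(scaling_state(firing_rate = 3, target_rate = 5)), 0)
  expect_equal(scaling_dG(scaling_state(firing_rate = 3, target_rate = 5,
                                        rate_constant = 2)), 4.0)

  # closed loop: R proportional to G; Euler integration converges to target
  st <- scaling_state(global_factor = 1, target_rate = 5, rate_constant = 0.5)
  G <- st$global_factor
  for (i in 1:400) {
    st$firing_rate <- 2 * G            # rate model: R = 2 G
    G <- G + 0.05 * scaling_dG(st)
    st$global_factor <- G
  }
  expect_equal(2 * G, 5, tolerance = 1e-3)
})

test_that("STDP kernel has the hard 40 ms window and is additive", {
  k <- stdp_kernel(potentiation_amp = 1, depression_amp = 1,
                   time_constant = 20, cutoff_window = 40)
  expect_equal(stdp_dw(numeric(0), c(10), k), 0)
  expect_equal(stdp_dw(c(10), numeric(0), k), 0)

  expect_equal(stdp_dw(0, 50, k), 0)               # dt = 50 >= 40: fails
  expect_equal(stdp_dw(0, 40, k), 0)               # boundary excluded
  expect_equal(stdp_dw(0, 10, k), exp(-0.5))       # dt = +10, tau = 20
  expect_equal(stdp_dw(10, 0, k), -exp(-0.5))      # reversed order: LTD
  expect_equal(stdp_dw(5, 5, k), 0)                # dt = 0 contributes 0

  # additivity over disjoint train segments
  pre <- c(0, 15, 200, 230); post <- c(8, 22, 210, 225)
  whole <- stdp_dw(pre, post, k)
  parts <- stdp_dw(pre[1:2], post[1:2], k) + stdp_dw(pre[3:4], post[3:4], k)
  expect_equal(whole, parts)
})

test_that("twin simulation settles at defaults and is seeded", {
  cfg <- twin_config()
  expect_equal(cfg$n_regions, 76L)
  expect_equal(cfg$coupling_strength, 0.015)
  expect_equal(cfg$hill_coefficient, 0.3)
  expect_equal(cfg$duration, 2000)

  res <- twin_simulate(cfg)
  expect_true(res$settled)
  expect_false(res$diverged)
  expect_true(is.finite(res$mean_synchrony))

  res2 <- twin_simulate(twin_config())
  expect_identical(res$trajectories, res2$trajectories)

  # uncoupled, noiseless: all regions decay to the logistic fixed point
  un <- twin_simulate(twin_config(n_regions = 10, coupling_strength = 0,
                                  noise_sd = 0, duration = 500))
  S0 <- 1 / (1 + exp(0.5 / 0.3))
  expect_equal(unname(un$final_state), rep(S0, 10), tolerance = 1e-4)
})

test_that("connectome fixture is symmetric, non-negative, zero-diagonal", {
  C <- dk_connectome()
  expect_equal(dim(C), c(76, 76))
  expect_true(isSymmetric(C))
  expect_true(all(C >= 0))
  expect_equal(diag(C), rep(0, 76))
  expect_identical(C, dk_connectome())
})
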