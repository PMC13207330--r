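test_that("posterior update is conjugate, convex, and deterministic", {
  # constant stream: threshold converges into a neighbourhood of c
  p <- bdws_posterior()
  for (i in 1:500) p <- update_posterior(p, 2.0)
  expect_lt(abs(p$theta - 2.0) / 2.0, 0.05)
  scale <- sqrt(p$b * (p$kappa + 1) / (p$a * p$kappa))
  expect_lt(scale, 0.05)

  # single update from a vague prior lands between prior mean and log y
  p1 <- update_posterior(bdws_posterior(mu0 = 0), exp(1))
  expect_between(p1$mu, 0, 1)

  # identical streams and priors give identical threshold sequences
  set.seed(2); y <- rlnorm(200)
  run <- function() {
    p <- bdws_posterior()
    vapply(y, function(yy) { p <<- update_posterior(p, yy); p$theta },
           numeric(1))
  }
  expect_identical(run(), run())

  # non-positive y rejected, posterior untouched
  p2 <- update_posterior(bdws_posterior(), 1.5)
  p3 <- update_posterior(p2, -1)
  expect_equal(p3$theta, p2$theta)
  expect_equal(p3$n_rejected, 1L)
})

test_that("reward decision implements the direction and tie rules", {
  expect_false(reward_decision(1, 1, "suppress"))
  expect_false(reward_decision(1, 1, "enhance"))
  expect_true(reward_decision(0.5, 1, "suppress"))
  expect_false(reward_decision(0.5, 1, "enhance"))
  expect_true(reward_decision(2, 1, "enhance"))
})

test_that("success rate summarizes trailing windows", {
  expect_equal(success_rate(rep(TRUE, 10)), 1.0)
  expect_equal(success_rate(rep(c(TRUE, FALSE), 10), 10), 0.5)
  expect_error(success_rate(logical(0)), "window")
  expect_error(success_rate(c(TRUE), 5), "window")
})

test_that("both backends hold the set point on stationary streams", {
  run_sp <- function(rho, backend, seed = 1) {
    set.seed(seed)
    y <- rlnorm(5000, meanlog = log(1.2), sdlog = 0.4)
    p <- bdws_posterior(rho_star = rho, backend = backend)
    rew <- logical(5000)
    for (t in seq_along(y)) {
      rew[t] <- reward_decision(y[t], p$theta, p$direction)
      p <- update_posterior(p, y[t])
    }
    mean(tail(rew, 2000))
  }
  for (backend in c("conjugate", "empirical")) {
    expect_lt(abs(run_sp(0.70, backend) - 0.70), 0.03)
    expect_lt(abs(run_sp(0.85, backend) - 0.85), 0.03)
  }
})

test_that("enhance direction holds its set point too", {
  set.seed(3)
  y <- rlnorm(4000, log(2), 0.5)
  p <- bdws_posterior(rho_star = 0.70, direction = "enhance")
  rew <- logical(4000)
  for (t in seq_along(y)) {
    rew[t] <- reward_decision(y[t], p$theta, p$direction)
    p <- update_posterior(p, y[t])
  }
  expect_lt(abs(mean(tail(rew, 1500)) - 0.70), 0.03)
})

test_that("adaptive controller recovers from a step change; static does not", {
  set.seed(7)
  y1 <- rlnorm(1000, log(1.2), 0.4)
  y2 <- rlnorm(1500, log(2.0), 0.4)     # location step: signal drifts up
  y <- c(y1, y2)
  p <- bdws_posterior()
  rew <- logical(length(y))
  for (t in seq_along(y)) {
    rew[t] <- reward_decision(y[t], p$theta, p$direction)
    p <- update_posterior(p, y[t])
  }
  # back within +-0.05 of the set point within 300 epochs of the shift
  expect_lt(abs(mean(rew[1151:1300]) - 0.70), 0.05)
  expect_lt(abs(mean(tail(rew, 500)) - 0.70), 0.05)

  st <- static_threshold(y1, 0.70)
  static_rate <- mean(y2 < st$theta)
  expect_gt(abs(static_rate - 0.70), 0.05)
})

test_that("information gain is the binary entropy with its symmetries", {
  expect_equal(information_gain(0.5), 1.0)
  expect_equal(information_gain(0), 0)
  expect_equal(information_gain(1), 0)
  h07 <- -0.7 * log2(0.7) - 0.3 * log2(0.3)
  expect_equal(information_gain(0.7), h07)
  expect_equal(round(information_gain(0.7), 4), 0.8813)

  grid <- seq(0, 1, by = 0.05)
  expect_equal(information_gain(grid), information_gain(1 - grid))
  expect_true(all(information_gain(grid) <= 1))
  expect_gt(information_gain(0.70), information_gain(0.85))
})

test_that("operating point subtracts the clinical offset", {
  expect_equal(operating_point(0.85, 0.15), 0.70)
  expect_equal(operating_point(0.85, 0), 0.85)
  expect_error(operating_point(0.85, 0.90), "between 0 and 1")
})

test_that("tier assignment follows the protocol bounds and plans", {
  hi <- assign_tier(90)
  expect_equal(hi$tier, "HighPerformance")
  expect_between(sum(hi$block_plan$minutes), 20, 30)

  med <- assign_tier(80)
  expect_equal(med$tier, "MediumPerformance")
  expect_equal(sum(med$block_plan$minutes), 20)

  hit <- assign_tier(70)
  expect_equal(hit$tier, "HIT")
  expect_equal(sum(hit$block_plan$minutes), 15)
  expect_equal(hit$block_plan$minutes, c(5, 5, 5))
  expect_equal(hit$block_plan$phase, c("active", "rest", "active"))

  # documented boundary resolution
  expect_equal(assign_tier(85)$tier, "HighPerformance")
  expect_equal(assign_tier(75)$tier, "MediumPerformance")
  expect_error(assign_tier(120), "0, 100")
})

test_that("HRV gate eases difficulty on drops and saturates at the cap", {
  p <- bdws_posterior()
  stable <- hrv_state(current = 42, baseline = 42)
  expect_equal(hrv_gate(stable, p)$rho_effective, p$rho_star)

  dropped <- hrv_state(current = 0.7 * 42, baseline = 42, drop_fraction = 0.2)
  p2 <- hrv_gate(dropped, p, ease_step = 0.05)
  expect_equal(p2$rho_effective, 0.75)

  for (i in 1:10) p2 <- hrv_gate(dropped, p2, ease_step = 0.05)
  expect_equal(p2$rho_effective, 0.9)
})
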