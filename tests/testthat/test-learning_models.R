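test_that("contingency-space coding follows the stated rule", {
  sched <- data.frame(cue = c(1, 1, 2, 2), outcome = c(0, 1, 0, 1))
  u <- encode_contingency_space(sched)
  expect_equal(u$u, c(1L, 0L, 0L, 1L))
  # counting oracle over the full default schedule: u is 1 with probability
  # 1 - p in cue1-high blocks and p in cue2-high blocks
  s <- default_schedule()
  uu <- encode_contingency_space(s)$u
  expected <- sum(vapply(split(s, s$block), function(b) {
    p1 <- b$p_resist_cue1[1]
    sum(b$cue == 1 & b$outcome == 0) + sum(b$cue == 2 & b$outcome == 1)
  }, numeric(1))) / nrow(s)
  expect_equal(mean(uu), expected)
  expect_equal(mean(uu), 0.35)  # counted by hand for the default blocks
})

test_that("RW trajectory matches the hand-iterated recursion", {
  expect_equal(rw_trajectory(c(1, 0, 1), alpha = 0)$v, rep(0.5, 3))
  tr1 <- rw_trajectory(c(1, 0, 0, 1), alpha = 1)
  expect_equal(tr1$v, c(0.5, 1, 0, 0))
  tr <- rw_trajectory(c(1, 1, 0), alpha = 0.25, return_final = TRUE)
  expect_equal(tr$v, c(0.5, 0.625, 0.71875), tolerance = 1e-15)
  expect_equal(attr(tr, "v_final"), 0.5390625, tolerance = 1e-15)
  expect_equal(tr$delta, c(1, 1, 0) - tr$v)
  expect_error(rw_trajectory(c(0, 1), alpha = 1.2), "alpha")
})

test_that("RW trajectories stay in [0,1] for any alpha and input", {
  set.seed(99)
  for (i in 1:25) {
    u <- rbinom(60, 1, runif(1))
    a <- runif(1)
    v <- rw_trajectory(u, a, v0 = runif(1))$v
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("HGF trajectories behave in the analytic limits", {
  u1 <- rep(1L, 60)
  v2 <- hgf2_trajectory(u1, omega2 = -2)$v
  expect_true(all(diff(v2) >= 0))
  expect_gt(v2[60], 0.9)
  v3 <- hgf3_trajectory(u1, kappa2 = 1)$v
  expect_true(all(diff(v3) >= 0))
  # frozen-learning limit: very negative evolution rate pins the belief
  u <- encode_contingency_space(default_schedule())$u
  fx <- hgf_fixed_params(sigma2_0 = 1e-4)
  vfrozen <- hgf2_trajectory(u, omega2 = -20, fixed = fx)$v
  expect_lt(max(abs(vfrozen - 0.5)), 0.05)
})

test_that("HGF updates agree with an independent recoding to 1e-10", {
  u <- encode_contingency_space(default_schedule())$u
  for (om in c(-5, -3, -1)) {
    expect_equal(hgf2_trajectory(u, om)$v, oracle_hgf2_v(u, om),
                 tolerance = 1e-10)
  }
  for (ka in c(0.3, 1, 2)) {
    expect_equal(hgf3_trajectory(u, ka)$v, oracle_hgf3_v(u, ka),
                 tolerance = 1e-10)
  }
})

test_that("compiled trajectories equal the reference R implementations", {
  u <- encode_contingency_space(default_schedule())$u
  fx <- hgf_fixed_params()
  fxv <- c(0.5, fx$mu2_0, fx$sigma2_0, fx$mu3_0, fx$sigma3_0, fx$omega2,
           fx$omega3)
  expect_equal(breathelearn:::traj_cpp(u, 0L, 0.3, fxv),
               rw_trajectory(u, 0.3)$v, tolerance = 1e-14)
  expect_equal(breathelearn:::traj_cpp(u, 1L, -2.5, fxv),
               hgf2_trajectory(u, -2.5)$v, tolerance = 1e-14)
  expect_equal(breathelearn:::traj_cpp(u, 2L, 1.4, fxv),
               hgf3_trajectory(u, 1.4)$v, tolerance = 1e-14)
  y <- rbinom(length(u), 1, 0.5)
  expect_equal(breathelearn:::loglik_cpp(u, y, 0L, 0.3, 2.5, fxv),
               response_loglik(rw_trajectory(u, 0.3)$v, y, 2.5),
               tolerance = 1e-12)
})

test_that("unit-square sigmoid response model evaluates correctly", {
  expect_equal(response_prob(0.5, 7.3), 0.5)
  vv <- seq(0.05, 0.95, by = 0.05)
  expect_equal(response_prob(vv, 1), vv, tolerance = 1e-12)
  expect_equal(response_prob(0.8, 2), 0.64 / 0.68, tolerance = 1e-12)
  # valid probability on a dense grid: p(1) + p(0) = 1 by construction of
  # the complement evaluated at 1 - v
  for (z in c(0, 0.5, 1, 3, 10, 100)) {
    expect_equal(response_prob(vv, z) + response_prob(1 - vv, z),
                 rep(1, length(vv)), tolerance = 1e-12)
  }
})

test_that("response log-likelihood sums the per-trial terms", {
  v <- c(0.2, 0.5, 0.9)
  y <- c(0, 1, 1)
  z <- 2
  p <- response_prob(v, z)
  expect_equal(response_loglik(v, y, z),
               sum(log(c(1 - p[1], p[2], p[3]))))
  expect_error(response_loglik(v, c(1, 0), z), "length")
  # finite even at extreme beliefs
  expect_true(is.finite(response_loglik(c(0, 1), c(0, 1), 50)))
})

test_that("opposite contingency coding yields identical stimulus space", {
  s <- default_schedule()
  u <- encode_contingency_space(s)$u
  tr_a <- rw_trajectory(u, 0.3)
  stim_a <- to_stimulus_space(tr_a, s$cue)
  # coding B: u' = 1 - u; by symmetry of the delta rule v' = 1 - v, and the
  # stimulus-space transform swaps its branches
  tr_b <- rw_trajectory(1L - u, 0.3)
  v_stim_b <- ifelse(s$cue == 1, 1 - tr_b$v, tr_b$v)
  d_stim_b <- ifelse(s$cue == 1, -tr_b$delta, tr_b$delta)
  expect_equal(stim_a$v_stim, v_stim_b, tolerance = 1e-12)
  expect_equal(stim_a$delta_stim, d_stim_b, tolerance = 1e-12)
})
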