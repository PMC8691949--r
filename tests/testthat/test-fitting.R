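test_that("MAP recovers the generating learning rate on average", {
  cohort <- make_rw_cohort(40, alpha = 0.3, zeta = 5, seed = 101)
  u <- encode_contingency_space(default_schedule())
  alphas <- vapply(cohort, function(ag) {
    fit_map(ag$y, u, "RW", options = fit_options(n_restarts = 3))$theta_map[["alpha"]]
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 0.3), 0.1)
})

test_that("coin-flip responders fit with small zeta and chance likelihood", {
  u <- encode_contingency_space(default_schedule())
  set.seed(55)
  zetas <- numeric(10)
  logliks <- numeric(10)
  for (i in 1:10) {
    y <- rbinom(80, 1, 0.5)
    f <- fit_map(y, u, "RW", options = fit_options(n_restarts = 3))
    zetas[i] <- f$theta_map[["zeta"]]
    logliks[i] <- f$loglik
  }
  expect_lt(median(zetas), 1.5)
  expect_lt(abs(median(logliks) - 80 * log(0.5)), 5)
})

test_that("a tightly peaked prior pins the MAP at the prior mean", {
  ag <- make_rw_cohort(1, 0.3, 5, seed = 7)[[1]]
  u <- encode_contingency_space(default_schedule())
  pr <- default_priors("RW", perc_mean = qlogis(0.7), perc_var = 1e-8,
                       zeta_mean = log(3), zeta_var = 1e-8)
  f <- fit_map(ag$y, u, "RW", priors = pr)
  expect_equal(f$theta_map[["alpha"]], 0.7, tolerance = 1e-3)
  expect_equal(f$theta_map[["zeta"]], 3, tolerance = 1e-2)
})

test_that("MLE equals MAP under an effectively flat prior", {
  ag <- make_rw_cohort(1, 0.35, 8, seed = 13)[[1]]
  u <- encode_contingency_space(default_schedule())
  mle <- fit_mle(ag$y, u, "RW", options = fit_options(n_restarts = 5))
  wide <- default_priors("RW", perc_var = 1e6, zeta_var = 1e6)
  map <- fit_map(ag$y, u, "RW", priors = wide,
                 options = fit_options(n_restarts = 5))
  expect_equal(mle$theta_map[["alpha"]], map$theta_map[["alpha"]],
               tolerance = 1e-2)
  expect_gte(mle$loglik, map$loglik - 1e-4)
})

test_that("zeta is flagged unidentifiable for a flat belief trajectory", {
  u <- encode_contingency_space(default_schedule())
  y <- rep(c(0L, 1L), 40)
  # alpha = 0 keeps v = 0.5 throughout; likelihood independent of zeta
  f <- fit_mle(y, u, "RW", options = fit_options(n_restarts = 2,
                                                 fix_zeta = NULL))
  if (f$theta_map[["alpha"]] < 1e-3) {
    expect_true(any(grepl("flat likelihood|boundary", f$flags)))
  }
  ll1 <- response_loglik(rep(0.5, 80), y, 1)
  ll2 <- response_loglik(rep(0.5, 80), y, 10)
  expect_equal(ll1, ll2)
})

test_that("MLE bias for alpha shrinks with longer sessions", {
  long_cfg <- blt_schedule_config(blocks = c(30, rep(10, 60), 50))
  long_sched <- generate_blt_schedule(long_cfg, seed = 3)
  expect_equal(nrow(long_sched), 680L)
  u80 <- encode_contingency_space(default_schedule())
  ulong <- encode_contingency_space(long_sched)
  bias <- function(sched, u, n) {
    est <- vapply(derive_seeds_for_tests(77, n), function(sd) {
      ag <- simulate_agent(sched, "RW", 0.3, 5, seed = sd)
      fit_mle(ag$y, u, "RW",
              options = fit_options(n_restarts = 3))$theta_map[["alpha"]]
    }, numeric(1))
    abs(mean(est) - 0.3)
  }
  expect_lt(bias(long_sched, ulong, 12), bias(default_schedule(), u80, 12) + 0.02)
})

test_that("priors are derived from holdout MLEs with a variance floor", {
  cohort <- make_rw_cohort(8, 0.3, 5, seed = 301)
  u <- encode_contingency_space(default_schedule())
  fits <- lapply(cohort, function(ag) {
    fit_mle(ag$y, u, "RW", options = fit_options(n_restarts = 3))
  })
  pr <- derive_priors(fits)
  ests <- vapply(fits, function(f) f$theta_transformed[1], numeric(1))
  ci <- mean(ests) + c(-1, 1) * qt(0.975, 7) * sd(ests) / sqrt(8)
  expect_true(pr$perc$mean >= ci[1] && pr$perc$mean <= ci[2])
  # identical holdout values floor the variance
  f1 <- fits[[1]]
  w <- capture_warnings(pr_deg <- derive_priors(list(f1, f1)))
  expect_match(w, "floored", all = TRUE)
  expect_equal(pr_deg$perc$var, 0.01)
  expect_equal(pr_deg$zeta$var, 0.01)
  expect_error(derive_priors(list()), "no holdout fits")
  expect_error(derive_priors(fits[1]), "at least two")
})

test_that("Laplace evidence matches the analytic Gaussian case", {
  # 1-parameter quadratic log-joint with curvature h: true log evidence is
  # logjoint(max) + 0.5 * log(2 pi / h)
  for (h in c(0.5, 2, 10)) {
    fake <- list(log_joint = -3.2, hessian = matrix(h))
    expect_equal(laplace_lme(fake), -3.2 + 0.5 * log(2 * pi / h),
                 tolerance = 1e-6)
  }
  # d = 0: no free parameters, evidence equals the log-likelihood
  expect_equal(laplace_lme(list(log_joint = -55.45, hessian = NULL)), -55.45)
  # non-positive-definite Hessian is ridge-regularised with a warning
  expect_warning(laplace_lme(list(log_joint = 0,
                                  hessian = matrix(-1))), "ridge")
})

test_that("widening the prior incurs an Occam penalty", {
  ag <- make_rw_cohort(1, 0.3, 5, seed = 401)[[1]]
  u <- encode_contingency_space(default_schedule())
  narrow <- fit_map(ag$y, u, "RW", priors = default_priors("RW"))
  wide <- fit_map(ag$y, u, "RW",
                  priors = default_priors("RW", perc_var = 100,
                                          zeta_var = 100))
  expect_lt(wide$lme, narrow$lme)
})

test_that("null model and likelihood-ratio exclusion work", {
  y <- rbinom(80, 1, 0.5)
  expect_equal(null_loglik(y), 80 * log(0.5), tolerance = 1e-12)
  # near-perfect fit is never excluded
  fake_fit <- list(loglik = -1, theta_transformed = c(a = 0, b = 0))
  lr <- lr_test_vs_null(fake_fit, y)
  expect_equal(lr$df, 2)
  expect_lt(lr$p, 1e-10)
  expect_false(lr$exclude)
  # fits below the null are floored with a warning
  bad <- list(loglik = 80 * log(0.5) - 3, theta_transformed = c(a = 0, b = 0))
  expect_warning(lr2 <- lr_test_vs_null(bad, y), "floored")
  expect_equal(lr2$statistic, 0)
  expect_true(lr2$exclude)
})

test_that("failed fits are reported, never silent", {
  u <- encode_contingency_space(default_schedule())
  f <- fit_map(rbinom(80, 1, 0.5), u, "RW",
               options = fit_options(n_restarts = 2))
  expect_true(is.finite(f$lme) || !f$converged)
  expect_s3_class(f, "blt_fit")
})
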