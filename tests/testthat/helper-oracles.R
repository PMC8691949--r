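# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths: the HGF oracle is a second, separate
# transcription of the published update equations; the fit oracle is a
# two-stage dense grid search; the SDT oracle maximises the binomial
# likelihood on a grid.

default_schedule <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_blt_schedule(seed = 42L)
    cache
  }
})

# Second coding of the two-level binary HGF update equations, written in
# state-vector style rather than scalar style.
oracle_hgf2_v <- function(u, omega2, mu2_0 = 0, sigma2_0 = 1) {
  state <- c(mu = mu2_0, sigma = sigma2_0)
  vapply(u, function(uk) {
    pred1 <- stats::plogis(state["mu"])
    pi_hat <- (state["sigma"] + exp(omega2))^-1
    precision <- pi_hat + pred1 * (1 - pred1)
    state <<- c(mu = unname(state["mu"] + (uk - pred1) / precision),
                sigma = unname(1 / precision))
    unname(pred1)
  }, numeric(1))
}

# Second coding of the three-level binary HGF.
oracle_hgf3_v <- function(u, kappa2, fx = hgf_fixed_params()) {
  st <- list(m2 = fx$mu2_0, s2 = fx$sigma2_0, m3 = fx$mu3_0, s3 = fx$sigma3_0)
  out <- numeric(length(u))
  for (i in seq_along(u)) {
    pred1 <- stats::plogis(st$m2)
    out[i] <- pred1
    vol <- exp(kappa2 * st$m3 + fx$omega2)
    pihat2 <- 1 / (st$s2 + vol)
    pi2 <- pihat2 + pred1 * (1 - pred1)
    m2new <- st$m2 + (u[i] - pred1) / pi2
    vape <- (1 / pi2 + (m2new - st$m2)^2) * pihat2 - 1
    pihat3 <- 1 / (st$s3 + exp(fx$omega3))
    wt <- vol * pihat2
    pi3 <- pihat3 + 0.5 * kappa2^2 * wt * (wt + (2 * wt - 1) * vape)
    st <- list(m2 = m2new, s2 = 1 / pi2,
               m3 = st$m3 + 0.5 * kappa2 * wt * vape / pi3, s3 = 1 / pi3)
  }
  out
}

# Dense two-stage grid search maximising the same RW log-joint as fit_map,
# in transformed space (logit alpha, log zeta), using only the pure-R
# model code.
oracle_grid_fit_rw <- function(y, u, priors) {
  logjoint <- function(la, lz) {
    v <- rw_trajectory(u, plogis(la))$v
    response_loglik(v, y, exp(lz)) +
      dnorm(la, priors$perc$mean, sqrt(priors$perc$var), log = TRUE) +
      dnorm(lz, priors$zeta$mean, sqrt(priors$zeta$var), log = TRUE)
  }
  stage <- function(la0, lz0, half, step) {
    la_g <- seq(la0 - half, la0 + half, by = step)
    lz_g <- seq(lz0 - half, lz0 + half, by = step)
    lj <- outer(la_g, lz_g, Vectorize(logjoint))
    b <- arrayInd(which.max(lj), dim(lj))
    c(la_g[b[1]], lz_g[b[2]])
  }
  best <- stage(0, 0.5, 5, 0.1)
  best <- stage(best[1], best[2], 0.12, 0.004)
  best <- stage(best[1], best[2], 0.005, 1e-4)
  c(logit_alpha = best[1], log_zeta = best[2],
    alpha = plogis(best[1]), zeta = exp(best[2]))
}

# Grid maximisation of the binomial likelihood of (hits, false alarms)
# over (d', c); the closed-form z-based indices must agree.
oracle_sdt_grid <- function(hits, misses, fa, cr) {
  ll <- function(d, cc) {
    hr <- pnorm(d / 2 - cc); far <- pnorm(-d / 2 - cc)
    dbinom(hits, hits + misses, hr, log = TRUE) +
      dbinom(fa, fa + cr, far, log = TRUE)
  }
  d_grid <- seq(-1, 5, by = 0.002)
  c_grid <- seq(-2, 2, by = 0.002)
  L <- outer(d_grid, c_grid, Vectorize(ll))
  best <- arrayInd(which.max(L), dim(L))
  c(d_prime = d_grid[best[1]], criterion_c = c_grid[best[2]])
}

# Small cohort of simulated RW agents reused across fitting tests.
make_rw_cohort <- function(n, alpha, zeta, seed, schedule = default_schedule()) {
  seeds <- derive_seeds_for_tests(seed, n)
  lapply(seeds, function(s) simulate_agent(schedule, "RW", alpha, zeta,
                                           seed = s))
}

new_traj <- function(v, delta) {
  structure(list(v = v, delta = delta, model = "RW", params = NULL),
            class = "belief_trajectory")
}

derive_seeds_for_tests <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(1e7, n)
}
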