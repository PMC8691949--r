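#' Encode a schedule in contingency space
#'
#' Because the two cues carry exactly mirrored outcome probabilities, a
#' single belief trajectory suffices if the outcome is coded relative to the
#' cue. The convention used here sets `u = 1` for "no resistance" after
#' cue 1 and for "resistance" after cue 2, and `u = 0` for the two other
#' cue-outcome combinations. The opposite convention yields identical
#' trajectories after back-transformation to stimulus space.
#'
#' @param schedule A `blt_schedule` (or any data frame with `cue` in
#'   \{1, 2\} and binary `outcome`).
#' @return A list of class `contingency_input` with elements `u` (binary
#'   vector), `cue`, and `outcome`.
#' @export
encode_contingency_space <- function(schedule) {
  if (!all(schedule$cue %in% c(1, 2))) {
    stop("schedule cues must be coded 1/2")
  }
  assert_binary(schedule$outcome, "outcome")
  u <- as.integer((schedule$cue == 1 & schedule$outcome == 0) |
                    (schedule$cue == 2 & schedule$outcome == 1))
  structure(list(u = u, cue = schedule$cue, outcome = schedule$outcome),
            class = "contingency_input")
}

new_belief_trajectory <- function(v, delta, model, params) {
  structure(list(v = v, delta = delta, model = model, params = params),
            class = "belief_trajectory")
}

#' Rescorla-Wagner belief trajectory
#'
#' Delta-rule learning of the outcome probability in contingency space:
#' `v(k+1) = v(k) + alpha * (u(k) - v(k))`, where `v(k)` is the prediction
#' held *before* observing trial `k`.
#'
#' @param u Binary outcome sequence in contingency space, or a
#'   `contingency_input`.
#' @param alpha Learning rate in `[0, 1]`.
#' @param v0 Initial belief; defaults to maximal uncertainty (0.5).
#' @param return_final If `TRUE`, attach the `N+1`-th posterior belief as
#'   attribute `v_final`.
#' @return A `belief_trajectory` with predictions `v` and prediction errors
#'   `delta = u - v`, both of length `length(u)`.
#' @examples
#' tr <- rw_trajectory(c(1, 1, 0), alpha = 0.25)
#' tr$v  # 0.5 0.625 0.71875
#' @export
rw_trajectory <- function(u, alpha, v0 = 0.5, return_final = FALSE) {
  if (inherits(u, "contingency_input")) u <- u$u
  assert_binary(u, "u")
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]")
  }
  assert_prob(v0, "v0")
  n <- length(u)
  v <- numeric(n)
  v[1] <- v0
  if (n > 1) {
    for (k in seq_len(n - 1)) v[k + 1] <- v[k] + alpha * (u[k] - v[k])
  }
  out <- new_belief_trajectory(v, u - v, "RW", c(alpha = alpha, v0 = v0))
  if (return_final) {
    attr(out, "v_final") <- v[n] + alpha * (u[n] - v[n])
  }
  out
}

#' Fixed parameters of the hierarchical Gaussian filter variants
#'
#' The study delegates these values to supplementary material that is not
#' reproduced here; the defaults below are reconstructions following the
#' binary-outcome conventions of the originating toolbox (version 5.3
#' semantics) and are overridable everywhere they are used.
#'
#' @param mu2_0,sigma2_0 Initial mean and variance of the level-2 belief.
#' @param mu3_0,sigma3_0 Initial mean and variance of the level-3
#'   (log-volatility) belief; used by the three-level variant only.
#' @param omega2 Level-2 evolution rate; free in the two-level variant and
#'   fixed in the three-level variant.
#' @param omega3 Level-3 evolution rate (three-level variant).
#' @param kappa2 Coupling of level 3 onto level 2; free in the three-level
#'   variant.
#' @return Named list of fixed parameters.
#' @export
hgf_fixed_params <- function(mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1,
                             sigma3_0 = 1, omega2 = -3, omega3 = -6,
                             kappa2 = 1) {
  list(mu2_0 = mu2_0, sigma2_0 = sigma2_0, mu3_0 = mu3_0,
       sigma3_0 = sigma3_0, omega2 = omega2, omega3 = omega3,
       kappa2 = kappa2)
}

#' Two-level hierarchical Gaussian filter trajectory (binary outcomes)
#'
#' Variational update equations for the two-level binary HGF. The level-2
#' tendency `mu2` generates the outcome probability through a logistic
#' sigmoid; its evolution rate `omega2` is the free parameter. The
#' trial-wise prediction `v(k)` is the sigmoid of the level-2 prediction
#' *before* trial `k`.
#'
#' @inheritParams rw_trajectory
#' @param omega2 Level-2 evolution rate (log-volatility), unbounded.
#' @param fixed Fixed-parameter list from [hgf_fixed_params()].
#' @return A `belief_trajectory` with `v`, `delta = u - v`, and the level-2
#'   posterior means/variances attached as attribute `levels`.
#' @export
hgf2_trajectory <- function(u, omega2, fixed = hgf_fixed_params()) {
  if (inherits(u, "contingency_input")) u <- u$u
  assert_binary(u, "u")
  stopifnot(is.finite(omega2))
  n <- length(u)
  v <- numeric(n)
  mu2 <- numeric(n)
  sigma2 <- numeric(n)
  m2 <- fixed$mu2_0
  s2 <- fixed$sigma2_0
  for (k in seq_len(n)) {
    muhat1 <- inv_logit(m2)
    v[k] <- muhat1
    pihat2 <- 1 / (s2 + exp(omega2))
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    if (!is.finite(pi2) || pi2 <= 0) {
      stop("trajectory invalid: non-positive level-2 precision at trial ", k)
    }
    m2 <- m2 + (u[k] - muhat1) / pi2
    s2 <- 1 / pi2
    mu2[k] <- m2
    sigma2[k] <- s2
  }
  out <- new_belief_trajectory(v, u - v, "HGF2", c(omega2 = omega2))
  attr(out, "levels") <- list(mu2 = mu2, sigma2 = sigma2)
  out
}

#' Three-level hierarchical Gaussian filter trajectory (binary outcomes)
#'
#' As [hgf2_trajectory()], with a third level tracking the log-volatility
#' of level 2. The level-2/3 coupling `kappa2` is the free parameter;
#' `omega2` and `omega3` are held at their fixed values. Updates that drive
#' the level-3 precision non-positive abort with a "trajectory invalid"
#' error, which the fitting routines treat as a rejected parameter setting.
#'
#' @inheritParams hgf2_trajectory
#' @param kappa2 Coupling strength of level 3 onto the level-2 volatility.
#' @return A `belief_trajectory`; level-2/3 states attached as `levels`.
#' @export
hgf3_trajectory <- function(u, kappa2, fixed = hgf_fixed_params()) {
  if (inherits(u, "contingency_input")) u <- u$u
  assert_binary(u, "u")
  stopifnot(is.finite(kappa2))
  n <- length(u)
  v <- numeric(n)
  mu2 <- numeric(n); sigma2 <- numeric(n)
  mu3 <- numeric(n); sigma3 <- numeric(n)
  m2 <- fixed$mu2_0; s2 <- fixed$sigma2_0
  m3 <- fixed$mu3_0; s3 <- fixed$sigma3_0
  om2 <- fixed$omega2; om3 <- fixed$omega3
  for (k in seq_len(n)) {
    muhat1 <- inv_logit(m2)
    v[k] <- muhat1
    expt <- exp(kappa2 * m3 + om2)
    pihat2 <- 1 / (s2 + expt)
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    if (!is.finite(pi2) || pi2 <= 0) {
      stop("trajectory invalid: non-positive level-2 precision at trial ", k)
    }
    m2new <- m2 + (u[k] - muhat1) / pi2
    # volatility prediction error at level 2
    da2 <- (1 / pi2 + (m2new - m2)^2) * pihat2 - 1
    pihat3 <- 1 / (s3 + exp(om3))
    w2 <- expt * pihat2
    pi3 <- pihat3 + 0.5 * kappa2^2 * w2 * (w2 + (2 * w2 - 1) * da2)
    if (!is.finite(pi3) || pi3 <= 0) {
      stop("trajectory invalid: non-positive level-3 precision at trial ", k)
    }
    m3 <- m3 + 0.5 * (1 / pi3) * kappa2 * w2 * da2
    s3 <- 1 / pi3
    m2 <- m2new
    s2 <- 1 / pi2
    mu2[k] <- m2; sigma2[k] <- s2
    mu3[k] <- m3; sigma3[k] <- s3
  }
  out <- new_belief_trajectory(v, u - v, "HGF3", c(kappa2 = kappa2))
  attr(out, "levels") <- list(mu2 = mu2, sigma2 = sigma2,
                              mu3 = mu3, sigma3 = sigma3)
  out
}

#' Compute a belief trajectory for any model in the model space
#'
#' @param u Contingency-space outcomes (binary vector or
#'   `contingency_input`).
#' @param model One of `"RW"`, `"HGF2"`, `"HGF3"`.
#' @param param The model's free perceptual parameter (`alpha`, `omega2`,
#'   or `kappa2`).
#' @param fixed Fixed parameters ([hgf_fixed_params()]); `v0` for the RW
#'   model may be supplied as `fixed$v0`.
#' @return A `belief_trajectory`.
#' @export
model_trajectory <- function(u, model, param, fixed = hgf_fixed_params()) {
  switch(model,
         RW = rw_trajectory(u, param, v0 = fixed$v0 %||% 0.5),
         HGF2 = hgf2_trajectory(u, param, fixed),
         HGF3 = hgf3_trajectory(u, param, fixed),
         stop("unknown model: ", model))
}

#' Unit-square sigmoid response probability
#'
#' Maps a prediction `v` onto the probability of choosing response 1:
#' `p(y = 1) = v^zeta / (v^zeta + (1 - v)^zeta)`. `zeta` sets how
#' deterministically choice follows belief: `zeta = 1` is probability
#' matching, `zeta -> Inf` is argmax, and `zeta = 0` yields 0.5 regardless
#' of `v`.
#'
#' @param v Predictions in `[0, 1]` (clamped internally away from 0/1).
#' @param zeta Decision-noise (inverse temperature) parameter, `>= 0`.
#' @return Vector of probabilities `p(y = 1)`.
#' @export
response_prob <- function(v, zeta) {
  assert_prob(v, "v")
  stopifnot(length(zeta) == 1L, is.finite(zeta), zeta >= 0)
  v <- clamp_prob(v)
  # v^z / (v^z + (1-v)^z) == logistic(z * logit(v)), which is stable for
  # large zeta where the direct powers over/underflow
  inv_logit(zeta * logit(v))
}

#' Response-model log-likelihood
#'
#' Total log-likelihood of binary decisions under the unit-square sigmoid
#' response model given a prediction trajectory.
#'
#' @param v A `belief_trajectory` or numeric prediction vector.
#' @param y Binary decisions, same length as `v`.
#' @param zeta Decision-noise parameter, `> 0` (0 allowed; gives chance
#'   likelihood).
#' @return A single finite log-likelihood value.
#' @export
response_loglik <- function(v, y, zeta) {
  if (inherits(v, "belief_trajectory")) v <- v$v
  assert_binary(y, "y")
  if (length(v) != length(y)) {
    stop("`v` and `y` have different lengths (", length(v), " vs ",
         length(y), ")")
  }
  p <- clamp_prob(response_prob(v, zeta))
  sum(y * log(p) + (1 - y) * log1p(-p))
}

#' @export
print.belief_trajectory <- function(x, ...) {
  cat(sprintf("%s belief trajectory (%d trials); params: %s\n", x$model,
              length(x$v),
              paste(names(x$params), signif(x$params, 4), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Serialize a belief trajectory to a tidy per-trial table
#'
#' @param x A `belief_trajectory`.
#' @param u Optional `contingency_input` to carry cue/outcome columns.
#' @param ... Unused.
#' @return A data frame with columns `trial`, (`cue`, `outcome`,) `u`, `v`,
#'   `delta`.
#' @export
as.data.frame.belief_trajectory <- function(x, u = NULL, ...) {
  out <- data.frame(trial = seq_along(x$v))
  if (!is.null(u) && inherits(u, "contingency_input")) {
    out$cue <- u$cue
    out$outcome <- u$outcome
    out$u <- u$u
  } else {
    out$u <- x$v + x$delta
  }
  out$v <- x$v
  out$delta <- x$delta
  out
}
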