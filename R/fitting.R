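# MAP / ML estimation of (perceptual parameter, zeta) in transformed space,
# Laplace approximation to the log model evidence, prior derivation from
# holdout fits, and the chance-null likelihood-ratio exclusion rule.

perc_name <- function(model) {
  switch(model, RW = "alpha", HGF2 = "omega2", HGF3 = "kappa2",
         stop("unknown model: ", model))
}

perc_transform <- function(model) {
  # logit keeps alpha in (0,1); the HGF evolution/coupling parameters are
  # unbounded and fitted on the identity scale; zeta is fitted on log scale
  switch(model, RW = "logit", HGF2 = "identity", HGF3 = "identity")
}

to_trans <- function(x, transform) {
  switch(transform, logit = logit(clamp_prob(x)), identity = x, log = log(x))
}

to_native <- function(x, transform) {
  switch(transform, logit = inv_logit(x), identity = x, log = exp(x))
}

#' Prior specification for model fitting
#'
#' Gaussian priors in transformed space: logit scale for the learning rate,
#' identity scale for the HGF evolution/coupling parameters, log scale for
#' the decision-noise parameter zeta. The defaults (used when no holdout
#' fits are available) centre the learning rate at 0.5 on the native scale,
#' the HGF parameters at their fixed-parameter defaults, and zeta at 2.
#'
#' @param model `"RW"`, `"HGF2"`, or `"HGF3"`.
#' @param perc_mean,perc_var Prior mean and variance of the transformed
#'   perceptual parameter.
#' @param zeta_mean,zeta_var Prior mean and variance of `log(zeta)`.
#' @return A list of class `prior_spec`.
#' @export
default_priors <- function(model, perc_mean = NULL, perc_var = 1,
                           zeta_mean = log(2), zeta_var = 1) {
  if (is.null(perc_mean)) {
    perc_mean <- switch(model, RW = 0, HGF2 = -3, HGF3 = 1)
  }
  structure(list(model = model,
                 perc = list(transform = perc_transform(model),
                             mean = perc_mean, var = perc_var),
                 zeta = list(transform = "log", mean = zeta_mean,
                             var = zeta_var)),
            class = "prior_spec")
}

#' Options controlling the quasi-Newton fits
#'
#' @param n_restarts Number of seeded multi-start optimisations (the
#'   response-model likelihood is multi-modal in zeta).
#' @param grad_tol Gradient-norm threshold below which an optimum is
#'   declared converged.
#' @param seed Seed for the restart starting points.
#' @param fix_zeta If non-`NULL`, hold zeta at this value and fit only the
#'   perceptual parameter.
#' @return A list of options for [fit_map()] / [fit_mle()].
#' @export
fit_options <- function(n_restarts = 10L, grad_tol = 1e-6, seed = 1L,
                        fix_zeta = NULL) {
  list(n_restarts = as.integer(n_restarts), grad_tol = grad_tol,
       seed = seed, fix_zeta = fix_zeta)
}

model_code <- function(model) {
  switch(model, RW = 0L, HGF2 = 1L, HGF3 = 2L, stop("unknown model: ", model))
}

fixed_vec <- function(fixed) {
  c(fixed$v0 %||% 0.5, fixed$mu2_0, fixed$sigma2_0, fixed$mu3_0,
    fixed$sigma3_0, fixed$omega2, fixed$omega3)
}

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Shared engine behind fit_map (gaussian priors) and fit_mle (flat prior).
fit_engine <- function(y, u, model, priors, options, fixed, flat_prior) {
  if (inherits(u, "contingency_input")) u <- u$u
  assert_binary(y, "y")
  assert_binary(u, "u")
  stopifnot(length(y) == length(u))
  mc <- model_code(model)
  fv <- fixed_vec(fixed)
  ui <- as.integer(u)
  yi <- as.integer(y)
  ptr <- priors$perc$transform
  fixz <- options$fix_zeta

  loglik_at <- function(theta) {
    perc <- to_native(theta[1], ptr)
    zeta <- if (is.null(fixz)) exp(theta[2]) else fixz
    ll <- loglik_cpp(ui, yi, mc, perc, zeta, fv)
    if (is.na(ll)) -Inf else ll
  }
  logprior_at <- function(theta) {
    if (flat_prior) return(0)
    lp <- stats::dnorm(theta[1], priors$perc$mean,
                       sqrt(priors$perc$var), log = TRUE)
    if (is.null(fixz)) {
      lp <- lp + stats::dnorm(theta[2], priors$zeta$mean,
                              sqrt(priors$zeta$var), log = TRUE)
    }
    lp
  }
  negobj <- function(theta) {
    val <- loglik_at(theta) + logprior_at(theta)
    if (!is.finite(val)) 1e10 else -val
  }

  d <- if (is.null(fixz)) 2L else 1L
  starts <- with_local_seed(options$seed, {
    s <- matrix(stats::rnorm(options$n_restarts * d), ncol = d)
    s[, 1] <- priors$perc$mean + s[, 1] * sqrt(max(priors$perc$var, 0.25))
    if (d == 2L) {
      s[, 2] <- priors$zeta$mean + s[, 2] * sqrt(max(priors$zeta$var, 0.25))
    }
    s[1, ] <- c(priors$perc$mean, if (d == 2L) priors$zeta$mean)  # prior mode
    s
  })
  # seed one restart from a coarse grid scan: the objective has a large
  # flat plateau at zeta -> 0 where gradient methods strand, so the best
  # grid point guards against missing narrow interior optima
  pgrid <- priors$perc$mean + seq(-3, 3, length.out = 13) *
    sqrt(max(priors$perc$var, 1))
  zgrid <- if (d == 2L) {
    priors$zeta$mean + seq(-3, 3, length.out = 9) *
      sqrt(max(priors$zeta$var, 1))
  } else 0
  gvals <- outer(pgrid, zgrid, Vectorize(function(a, b) {
    negobj(if (d == 2L) c(a, b) else a)
  }))
  gb <- arrayInd(which.min(gvals), dim(gvals))
  starts <- rbind(starts, c(pgrid[gb[1]], if (d == 2L) zgrid[gb[2]]))

  best <- NULL
  n_used <- 0L
  for (r in seq_len(nrow(starts))) {
    n_used <- r
    res <- tryCatch(
      stats::optim(starts[r, ], negobj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || best$value >= 1e10) {
    return(structure(list(model = model, converged = FALSE,
                          theta_map = NULL, loglik = NA_real_,
                          log_joint = NA_real_, lme = NA_real_,
                          hessian = NULL, hessian_logdet = NA_real_,
                          n_restarts_used = n_used,
                          flags = "all restarts failed"),
                     class = "blt_fit"))
  }

  theta <- best$par
  gnorm <- sqrt(sum(num_grad(negobj, theta)^2))
  converged <- is.finite(gnorm) && gnorm < max(options$grad_tol, 1e-3)
  # 1e-3 guards against finite-difference noise dominating the nominal
  # tolerance; the optimizer's own convergence code is also honoured
  converged <- converged || best$convergence == 0

  loglik <- loglik_at(theta)
  log_joint <- loglik + logprior_at(theta)
  H <- tryCatch(stats::optimHess(theta, negobj), error = function(e) NULL)

  native <- c(to_native(theta[1], ptr),
              if (is.null(fixz)) exp(theta[2]) else fixz)
  names(native) <- c(perc_name(model), "zeta")
  theta_named <- theta
  names(theta_named) <- c(paste0(ptr, "_", perc_name(model)),
                          if (is.null(fixz)) "log_zeta")

  flags <- character(0)
  if (model == "RW" && (native[1] < 1e-3 || native[1] > 1 - 1e-3)) {
    flags <- c(flags, "boundary estimate for alpha")
  }
  fit <- structure(list(model = model, theta_map = native,
                        theta_transformed = theta_named, loglik = loglik,
                        log_joint = log_joint, lme = NA_real_,
                        hessian = H, hessian_logdet = NA_real_,
                        converged = converged, n_restarts_used = n_used,
                        flat_prior = flat_prior, flags = flags),
                   class = "blt_fit")
  lme <- tryCatch(laplace_lme(fit), warning = function(w) {
    suppressWarnings(laplace_lme(fit))
  }, error = function(e) NA_real_)
  fit$lme <- lme
  if (!is.null(H) && nrow(H) > 0) {
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) fit$hessian_logdet <- sum(log(ev))
  }
  fit
}

#' Maximum a posteriori fit of a learning model
#'
#' Quasi-Newton (BFGS) maximisation of the log-joint in transformed
#' parameter space with seeded multi-start, Gaussian priors, and a Laplace
#' approximation to the log model evidence at the optimum.
#'
#' @param y Binary decisions in contingency space.
#' @param u Contingency-space outcomes (vector or `contingency_input`).
#' @param model `"RW"`, `"HGF2"`, or `"HGF3"`.
#' @param priors A `prior_spec` ([default_priors()] / [derive_priors()]).
#' @param options Optimisation options ([fit_options()]).
#' @param fixed Fixed model parameters ([hgf_fixed_params()]).
#' @return A list of class `blt_fit`: `theta_map` (native-space estimates),
#'   `theta_transformed`, `loglik`, `log_joint`, `lme`, `hessian`,
#'   `hessian_logdet`, `converged`, `n_restarts_used`, `flags`.
#' @export
fit_map <- function(y, u, model, priors = default_priors(model),
                    options = fit_options(), fixed = hgf_fixed_params()) {
  stopifnot(inherits(priors, "prior_spec"))
  fit_engine(y, u, model, priors, options, fixed, flat_prior = FALSE)
}

#' Maximum likelihood fit of a learning model
#'
#' As [fit_map()] with a flat (improper) prior; used to derive empirical
#' priors from a holdout cohort. Boundary estimates of the learning rate
#' are flagged. When the belief trajectory is flat at 0.5 (e.g. an
#' `alpha = 0` agent) the likelihood carries no information about zeta and
#' a flat-likelihood flag is raised.
#'
#' @inheritParams fit_map
#' @return A `blt_fit` (its `lme` is reported but meaningless under the
#'   improper prior).
#' @export
fit_mle <- function(y, u, model, options = fit_options(),
                    fixed = hgf_fixed_params()) {
  priors <- default_priors(model)
  fit <- fit_engine(y, u, model, priors, options, fixed, flat_prior = TRUE)
  if (!is.null(fit$theta_map)) {
    uu <- if (inherits(u, "contingency_input")) u$u else u
    v <- model_trajectory(uu, model, fit$theta_map[1], fixed)$v
    if (max(abs(v - 0.5)) < 1e-6) {
      fit$flags <- c(fit$flags,
                     "flat likelihood: v = 0.5 throughout, zeta unidentifiable")
    }
  }
  fit
}

#' Derive empirical priors from holdout fits
#'
#' Transformed-space means and variances of maximum-likelihood estimates
#' across a holdout cohort become the prior means and variances used for
#' the main cohort.
#'
#' @param holdout_fits A list of `blt_fit` objects for one model (at least
#'   two).
#' @param min_var Variance floor applied when the holdout estimates are
#'   (near-)degenerate.
#' @return A `prior_spec`.
#' @export
derive_priors <- function(holdout_fits, min_var = 0.01) {
  if (length(holdout_fits) == 0) stop("no holdout fits supplied")
  if (length(holdout_fits) < 2) stop("need at least two holdout fits")
  model <- holdout_fits[[1]]$model
  th <- t(vapply(holdout_fits, function(f) {
    stopifnot(identical(f$model, model))
    tt <- f$theta_transformed
    if (length(tt) == 1L) tt <- c(tt, NA_real_)
    tt
  }, numeric(2)))
  pv <- stats::var(th[, 1])
  zv <- if (all(is.na(th[, 2]))) NA_real_ else stats::var(th[, 2])
  if (!is.finite(pv) || pv < min_var) {
    warning("holdout variance for the perceptual parameter floored at ",
            min_var)
    pv <- min_var
  }
  if (is.finite(zv) && zv < min_var) {
    warning("holdout variance for log(zeta) floored at ", min_var)
    zv <- min_var
  }
  out <- default_priors(model)
  out$perc$mean <- mean(th[, 1])
  out$perc$var <- pv
  if (is.finite(zv)) {
    out$zeta$mean <- mean(th[, 2], na.rm = TRUE)
    out$zeta$var <- zv
  }
  out
}

#' Laplace approximation to the log model evidence
#'
#' `lme = log-joint(MAP) + (d/2) log(2 pi) - 0.5 log det(H)`, where `H` is
#' the (finite-difference) Hessian of the negative log-joint at the MAP
#' estimate. A non-positive-definite Hessian is ridge-regularised with a
#' warning; `d = 0` (no free parameters) returns the log-likelihood
#' unchanged.
#'
#' @param fit A `blt_fit`, or any list with elements `log_joint` and
#'   `hessian` (a d x d matrix; `NULL` or 0 x 0 means d = 0).
#' @return The scalar LME.
#' @export
laplace_lme <- function(fit) {
  H <- fit$hessian
  if (is.null(H) || length(H) == 0L) return(fit$log_joint)
  H <- as.matrix(H)
  d <- nrow(H)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    ridge <- abs(min(ev)) + 1e-6
    warning("Hessian not positive definite; ridge-regularised (ridge = ",
            signif(ridge, 3), ")")
    ev <- ev + ridge
    if (any(ev <= 0)) stop("Hessian singular after regularisation; LME undefined")
  }
  fit$log_joint + d / 2 * log(2 * pi) - 0.5 * sum(log(ev))
}

#' Log-likelihood of the chance null model
#'
#' The null model predicts every response with probability 0.5, so the
#' log-likelihood is `N log(0.5)` regardless of the data.
#'
#' @param y Binary decisions.
#' @return Scalar null log-likelihood.
#' @export
null_loglik <- function(y) {
  assert_binary(y, "y")
  length(y) * log(0.5)
}

#' Likelihood-ratio test of a fitted model against chance
#'
#' Subjects whose fitted model does not beat the chance null at p < 0.05
#' are flagged for exclusion from model-based analyses.
#'
#' @param fit A converged `blt_fit`.
#' @param y The binary decisions the model was fitted to.
#' @param df Degrees of freedom; defaults to the number of fitted
#'   parameters (2: the perceptual parameter and zeta).
#' @return A list with `statistic`, `df`, `p`, and `exclude`
#'   (`TRUE` when p > 0.05).
#' @export
lr_test_vs_null <- function(fit, y, df = NULL) {
  l0 <- null_loglik(y)
  if (is.null(df)) df <- length(fit$theta_transformed)
  stat <- 2 * (fit$loglik - l0)
  if (is.na(stat)) stop("fit has no log-likelihood (did it converge?)")
  if (stat < 0) {
    warning("fitted log-likelihood below the null; statistic floored at 0")
    stat <- 0
  }
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, exclude = p > 0.05)
}

#' @export
print.blt_fit <- function(x, ...) {
  if (is.null(x$theta_map)) {
    cat(sprintf("%s fit: FAILED (%s)\n", x$model,
                paste(x$flags, collapse = "; ")))
    return(invisible(x))
  }
  cat(sprintf("%s fit: %s; loglik = %.3f, LME = %.3f, converged = %s\n",
              x$model,
              paste(names(x$theta_map), signif(x$theta_map, 4), sep = "=",
                    collapse = ", "),
              x$loglik, x$lme, x$converged))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
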