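# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic operations in the package
# route their randomness through this so that no function touches global
# RNG state as a side effect.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream of child seeds from one master seed; keeps every derived
# seed inside 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_binary <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must be a binary (0/1) vector without NAs", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_prob <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# logit / inverse-logit used by the fitting transforms
logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Clamp probabilities away from 0/1 so log-likelihoods stay finite.
clamp_prob <- function(p, eps = 1e-8) pmin(pmax(p, eps), 1 - eps)
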