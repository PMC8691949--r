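#' Simulate a learning agent on a task schedule
#'
#' Draws binary prediction responses from the unit-square sigmoid response
#' model applied to the agent's trial-wise belief trajectory under the
#' chosen perceptual model.
#'
#' @param schedule A `blt_schedule`.
#' @param model `"RW"`, `"HGF2"`, or `"HGF3"`.
#' @param param The free perceptual parameter (`alpha`, `omega2`, `kappa2`).
#' @param zeta Decision-noise parameter, `>= 0` (`0` produces pure
#'   guessing).
#' @param seed Integer seed for the response draws.
#' @param fixed Fixed parameters ([hgf_fixed_params()]).
#' @return A list of class `agent_sim` with `y` (binary responses in
#'   contingency space), `u` (the `contingency_input`), `trajectory` (the
#'   latent `belief_trajectory`), `p` (trial-wise response probabilities),
#'   and the generating spec.
#' @export
simulate_agent <- function(schedule, model, param, zeta, seed = 1L,
                           fixed = hgf_fixed_params()) {
  stopifnot(zeta >= 0)
  u <- encode_contingency_space(schedule)
  traj <- model_trajectory(u, model, param, fixed)
  p <- response_prob(traj$v, zeta)
  y <- with_local_seed(seed, as.integer(stats::runif(length(p)) < p))
  structure(list(y = y, u = u, trajectory = traj, p = p,
                 spec = list(model = model, param = param, zeta = zeta,
                             seed = seed)),
            class = "agent_sim")
}

#' Specification of a simulated filter-detection observer
#'
#' The observer is an equal-variance signal-detection agent whose
#' sensitivity grows linearly with the inspiratory filter load:
#' `d'(filters) = slope * filters`. On each trial it sees evidence
#' `x ~ Normal(+-d'/2, 1)` and answers "yes" iff `x > criterion`.
#' Confidence is a monotone map of `|x - criterion|` (deciles of the folded
#' standard-normal CDF onto 1..10), optionally degraded by Gaussian
#' metacognitive noise added before binning.
#'
#' @param slope Increase in d' per filter; must be `> 0`.
#' @param criterion Type-1 decision criterion (0 = unbiased).
#' @param conf_noise SD of Gaussian jitter on the confidence evidence
#'   (0 = metacognitively ideal).
#' @return A list of class `fdt_observer`.
#' @export
fdt_observer <- function(slope = 0.3, criterion = 0, conf_noise = 0.3) {
  if (!is.numeric(slope) || slope <= 0) {
    stop("`slope` must be positive: the observer could never reach the ",
         "target accuracy band otherwise")
  }
  structure(list(slope = slope, criterion = criterion,
                 conf_noise = conf_noise),
            class = "fdt_observer")
}

#' Simulate a filter detection task session under a staircase
#'
#' Reconstruction of the task's adapted staircase: a search phase starts at
#' one filter and adjusts the filter count in mini-blocks until running
#' accuracy falls inside the target band, after which a "constant" phase of
#' `n_constant` trials runs at the settled filter count, with a +-1 filter
#' adjustment whenever trailing 10-trial accuracy leaves the band.
#'
#' @param observer An [fdt_observer()].
#' @param seed Integer seed.
#' @param n_constant Number of constant-phase trials (default 60).
#' @param band Target accuracy band (default `c(0.60, 0.85)`).
#' @param miniblock Search-phase mini-block length.
#' @param max_search_blocks Cap on search mini-blocks before the constant
#'   phase starts regardless.
#' @param max_filters Upper cap on the filter count.
#' @param start_filters Filter count the search phase starts from (also the
#'   constant-phase level when `max_search_blocks = 0`).
#' @param adjust_constant Whether the constant phase applies the trailing
#'   +-1 adjustment; disable to probe a fixed filter level.
#' @return A `data.frame` of class `fdt_session` with per-trial columns
#'   `trial`, `phase` ("search"/"constant"), `filter_count`,
#'   `signal_present`, `response_yes`, `confidence` (1-10), `correct`.
#' @export
simulate_fdt_observer <- function(observer = fdt_observer(), seed = 1L,
                                  n_constant = 60L, band = c(0.60, 0.85),
                                  miniblock = 10L, max_search_blocks = 10L,
                                  max_filters = 12L, start_filters = 1L,
                                  adjust_constant = TRUE) {
  stopifnot(inherits(observer, "fdt_observer"))
  run_trials <- function(n, filters) {
    dprime <- observer$slope * filters
    signal <- as.integer(stats::runif(n) < 0.5)
    x <- stats::rnorm(n, mean = ifelse(signal == 1, dprime / 2, -dprime / 2))
    yes <- as.integer(x > observer$criterion)
    dist <- abs(x - observer$criterion)
    if (observer$conf_noise > 0) {
      dist <- pmax(dist + stats::rnorm(n, sd = observer$conf_noise), 0)
    }
    # deciles of the folded standard-normal CDF -> ratings 1..10
    conf <- pmin(1L + as.integer(floor(10 * (2 * stats::pnorm(dist) - 1))),
                 10L)
    data.frame(filter_count = filters, signal_present = signal,
               response_yes = yes, confidence = conf,
               correct = as.integer(yes == signal))
  }

  with_local_seed(seed, {
    filters <- as.integer(start_filters)
    search <- list()
    for (b in seq_len(max_search_blocks)) {
      blk <- run_trials(miniblock, filters)
      search[[b]] <- blk
      acc <- mean(blk$correct)
      if (acc < band[1]) {
        filters <- min(filters + 1L, max_filters)
      } else if (acc > band[2]) {
        if (filters == 1L) break  # ceiling case: settle at the minimum load
        filters <- filters - 1L
      } else {
        break
      }
    }
    search <- if (length(search)) do.call(rbind, search) else NULL
    if (!is.null(search)) search$phase <- "search"

    const <- run_trials(n_constant, filters)
    # trailing-10 accuracy check with +-1 adjustment within the phase
    for (k in if (adjust_constant) seq_len(n_constant) else integer(0)) {
      if (k >= 10L && k < n_constant) {
        acc <- mean(const$correct[(k - 9L):k])
        newf <- const$filter_count[k]
        if (acc < band[1]) newf <- min(newf + 1L, max_filters)
        if (acc > band[2]) newf <- max(newf - 1L, 1L)
        if (newf != const$filter_count[k]) {
          redo <- run_trials(n_constant - k, newf)
          const <- rbind(const[seq_len(k), ], redo)
        }
      }
    }
    const$phase <- "constant"

    out <- if (is.null(search)) const else rbind(search, const)
    out$trial <- seq_len(nrow(out))
    out <- out[, c("trial", "phase", "filter_count", "signal_present",
                   "response_yes", "confidence", "correct")]
    attr(out, "observer") <- observer
    attr(out, "seed") <- seed
    class(out) <- c("fdt_session", "data.frame")
    out
  })
}

#' Simulate a bank of filter-detection observers
#'
#' Draws observers with heterogeneous sensitivity slopes and criteria
#' (log-normal / normal population distributions) and runs each through the
#' staircase. Used for calibration checks of the downstream metacognition
#' metrics and for the staircase accuracy contract.
#'
#' @param n Number of observers.
#' @param seed Master seed; per-observer seeds are derived from it.
#' @param slope_meanlog,slope_sdlog Log-normal population parameters of the
#'   d'-per-filter slope.
#' @param criterion_sd SD of the population criterion (mean 0).
#' @param conf_noise Metacognitive noise common to all observers.
#' @param ... Passed to [simulate_fdt_observer()].
#' @return A list of `fdt_session` objects.
#' @export
simulate_fdt_bank <- function(n = 100L, seed = 1L,
                              slope_meanlog = log(0.3), slope_sdlog = 0.25,
                              criterion_sd = 0.15, conf_noise = 0.3, ...) {
  seeds <- derive_seeds(seed, 2L * n)
  pop <- with_local_seed(seeds[1], {
    data.frame(slope = stats::rlnorm(n, slope_meanlog, slope_sdlog),
               criterion = stats::rnorm(n, 0, criterion_sd))
  })
  lapply(seq_len(n), function(i) {
    obs <- fdt_observer(slope = pop$slope[i], criterion = pop$criterion[i],
                        conf_noise = conf_noise)
    simulate_fdt_observer(obs, seed = seeds[n + i], ...)
  })
}

#' Measure names of the multimodal cohort table
#'
#' Four affective questionnaires, four interoceptive questionnaires, four
#' filter-detection-task measures, and four peak anterior-insula activity
#' values (positive/negative prediction certainty and prediction errors).
#'
#' @return Character vector of 16 measure names.
#' @export
multimodal_measures <- function() {
  c("STAI_S", "GAD7", "ASI", "CES_D",
    "MAIA", "BPQ", "PCS_B", "PVQ_B",
    "FDT_threshold", "FDT_c", "FDT_confidence", "FDT_Mratio",
    "aIns_pred_pos", "aIns_pred_neg", "aIns_PE_pos", "aIns_PE_neg")
}

#' Default generative configuration for the multimodal cohort
#'
#' Group effects (in noise-SD units, moderate minus low anxiety) and factor
#' loadings emulate the qualitative pattern reported for a low/moderate
#' trait-anxiety cohort: large shifts on the affective questionnaires,
#' moderate shifts on most interoceptive questionnaires (none on vigilance
#' after correction), small shifts on perceptual threshold and confidence,
#' and none on brain measures. A dominant negative-affect factor loads on
#' the questionnaire and metacognition measures, and a second, weaker
#' factor ties the four brain measures together.
#'
#' @param n_per_group Two group sizes (low, moderate).
#' @param group_effects Named numeric vector of group mean shifts per
#'   measure.
#' @param loadings 16 x k loadings matrix (rows named by measure).
#' @param noise_sd Residual noise SD.
#' @return A list understood by [generate_multimodal_cohort()].
#' @export
multimodal_config <- function(n_per_group = c(30L, 30L),
                              group_effects = NULL, loadings = NULL,
                              noise_sd = 1) {
  m <- multimodal_measures()
  if (is.null(group_effects)) {
    group_effects <- stats::setNames(numeric(16), m)
    group_effects[c("STAI_S", "GAD7", "ASI", "CES_D")] <- 1.5
    group_effects["MAIA"] <- -1.1
    group_effects["BPQ"] <- 0.7
    group_effects["PCS_B"] <- 0.9
    group_effects["PVQ_B"] <- 0.4
    group_effects["FDT_threshold"] <- 0.6
    group_effects["FDT_c"] <- -0.3
    group_effects["FDT_confidence"] <- -0.55
  }
  if (is.null(loadings)) {
    loadings <- matrix(0, 16, 2, dimnames = list(m, c("negative_affect",
                                                      "insula_reactivity")))
    loadings[c("STAI_S", "GAD7", "ASI", "CES_D"), 1] <- 0.9
    loadings["MAIA", 1] <- -0.7
    loadings[c("BPQ", "PCS_B"), 1] <- 0.7
    loadings["PVQ_B", 1] <- 0.4
    loadings["FDT_threshold", 1] <- 0.3
    loadings["FDT_confidence", 1] <- -0.35
    loadings["FDT_Mratio", 1] <- -0.3
    loadings[c("aIns_pred_pos", "aIns_pred_neg"), 2] <- 0.7
    loadings[c("aIns_PE_pos", "aIns_PE_neg"), 2] <- 0.5
    loadings["FDT_Mratio", 2] <- 0.3
  }
  list(n_per_group = n_per_group, group_effects = group_effects,
       loadings = loadings, noise_sd = noise_sd)
}

#' Generate a synthetic multimodal cohort table
#'
#' Each measure is `group effect + loadings x latent factors + Gaussian
#' noise`, with independent standard-normal latent factors per subject.
#'
#' @param config Configuration from [multimodal_config()].
#' @param seed Integer seed.
#' @return A `data.frame` of class `multimodal_table` with `subject_id`,
#'   `group` (factor low/moderate), and the 16 measure columns.
#' @export
generate_multimodal_cohort <- function(config = multimodal_config(),
                                       seed = 1L) {
  m <- multimodal_measures()
  L <- config$loadings
  if (!is.matrix(L) || nrow(L) != length(m)) {
    stop("`loadings` must be a matrix with ", length(m),
         " rows (one per measure); got ",
         paste(dim(L), collapse = " x "))
  }
  eff <- config$group_effects
  if (is.null(names(eff)) || !all(m %in% names(eff))) {
    stop("`group_effects` must be named by the 16 measures")
  }
  n1 <- config$n_per_group[1]
  n2 <- config$n_per_group[2]
  n <- n1 + n2
  group <- factor(rep(c("low", "moderate"), c(n1, n2)),
                  levels = c("low", "moderate"))
  X <- with_local_seed(seed, {
    factors <- matrix(stats::rnorm(n * ncol(L)), n, ncol(L))
    noise <- matrix(stats::rnorm(n * length(m), sd = config$noise_sd), n,
                    length(m))
    shift <- outer(as.integer(group == "moderate"), eff[m])
    shift + factors %*% t(L[m, , drop = FALSE]) + noise
  })
  colnames(X) <- m
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), group = group,
                    X, check.names = FALSE)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("multimodal_table", "data.frame")
  out
}
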