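# Back-transformation of fitted trajectories into stimulus space, valence
# splits into certainty / error magnitudes, model-based event tables for
# neuroimaging software, representative-subject selection, and validation
# of a fitted trajectory on unseen cohorts.

#' Transform a belief trajectory into stimulus space
#'
#' Contingency-space predictions refer to the cue-relative outcome coding;
#' stimulus space refers to the physical outcome, with `v_stim = 1` a
#' maximal prediction of "no resistance". For cue 1 the identity applies,
#' for cue 2 the mirror: `v_stim = 1 - v`, `delta_stim = -delta`. The
#' result is invariant to which contingency coding was used for fitting.
#'
#' @param trajectory A `belief_trajectory` (contingency space).
#' @param cues Cue sequence (1/2) aligned with the trajectory.
#' @return A data frame of class `stimulus_trajectory`: `trial`, `cue`,
#'   `v_stim`, `delta_stim`, `v_pos`, `v_neg`, `delta_pos`, `delta_neg`,
#'   and `valence` ("positive" = no-resistance prediction, "negative" =
#'   resistance prediction, "neutral" at the 0.5 boundary).
#' @export
to_stimulus_space <- function(trajectory, cues) {
  v <- if (inherits(trajectory, "belief_trajectory")) trajectory$v else trajectory$v
  delta <- trajectory$delta
  if (length(cues) != length(v)) {
    stop("`cues` (", length(cues), ") and trajectory (", length(v),
         ") have different lengths")
  }
  stopifnot(all(cues %in% c(1, 2)))
  v_stim <- ifelse(cues == 1, v, 1 - v)
  delta_stim <- ifelse(cues == 1, delta, -delta)
  cert <- split_certainty(v_stim)
  pe <- split_prediction_error(delta_stim)
  out <- data.frame(trial = seq_along(v), cue = cues, v_stim = v_stim,
                    delta_stim = delta_stim, v_pos = cert$v_pos,
                    v_neg = cert$v_neg, delta_pos = pe$delta_pos,
                    delta_neg = pe$delta_neg,
                    valence = ifelse(v_stim > 0.5, "positive",
                                     ifelse(v_stim < 0.5, "negative",
                                            "neutral")))
  class(out) <- c("stimulus_trajectory", "data.frame")
  out
}

#' Split stimulus-space predictions into valenced certainty magnitudes
#'
#' Certainty is the absolute deviation of the stimulus-space prediction
#' from maximal uncertainty (0.5), assigned to the positive
#' (no-resistance) stream when `v_stim > 0.5` and to the negative
#' (resistance) stream when `v_stim < 0.5`. The boundary `v_stim = 0.5`
#' contributes zero to both, which preserves the exact reconstruction
#' `v_stim = 0.5 + v_pos - v_neg`.
#'
#' @param v_stim Stimulus-space predictions in `[0, 1]`.
#' @return List with `v_pos` and `v_neg`, both in `[0, 0.5]`.
#' @export
split_certainty <- function(v_stim) {
  assert_prob(v_stim, "v_stim")
  list(v_pos = ifelse(v_stim > 0.5, v_stim - 0.5, 0),
       v_neg = ifelse(v_stim < 0.5, 0.5 - v_stim, 0))
}

#' Split stimulus-space prediction errors into valenced magnitudes
#'
#' Positive (no-resistance) prediction errors keep their value; negative
#' (resistance) prediction errors are sign-flipped; zero contributes to
#' neither stream. Reconstruction `delta_stim = delta_pos - delta_neg`
#' holds exactly.
#'
#' @param delta_stim Stimulus-space prediction errors in `[-1, 1]`.
#' @return List with `delta_pos` and `delta_neg`, both in `[0, 1]`.
#' @export
split_prediction_error <- function(delta_stim) {
  if (any(abs(delta_stim) > 1 + 1e-12)) stop("`delta_stim` must lie in [-1, 1]")
  list(delta_pos = ifelse(delta_stim > 0, delta_stim, 0),
       delta_neg = ifelse(delta_stim < 0, -delta_stim, 0))
}

#' Build the model-based event table for one subject
#'
#' Emits the eight task regressors as a BIDS-style events table (onset,
#' duration, trial_type, modulation): a cue regressor (magnitude 1, one row
#' per trial), positive/negative prediction regressors (0.5 s at cue onset,
#' modulated by the valenced certainty), no-resistance/resistance stimulus
#' regressors (magnitude 1 over the stimulus period), positive/negative
#' prediction-error regressors (0.5 s at stimulus onset, modulated by the
#' valenced error magnitude), and a rating-period regressor (magnitude 1).
#' Trials whose modulation is exactly zero are retained with modulation 0
#' rather than dropped, so row counts are fully determined by the schedule.
#'
#' @param schedule The `blt_schedule` the subject performed.
#' @param stim_traj The subject's `stimulus_trajectory`.
#' @param pred_duration,pe_duration Durations (s) of the prediction and
#'   prediction-error regressors.
#' @return A data frame of class `event_table` with columns `onset`,
#'   `duration`, `trial_type`, `modulation`, sorted by onset within
#'   regressor.
#' @export
build_event_table <- function(schedule, stim_traj, pred_duration = 0.5,
                              pe_duration = 0.5) {
  stopifnot(nrow(schedule) == nrow(stim_traj))
  pos <- stim_traj$v_stim > 0.5
  neg <- stim_traj$v_stim < 0.5
  resist <- schedule$outcome == 1
  mk <- function(onset, duration, type, modulation) {
    data.frame(onset = onset, duration = duration, trial_type = type,
               modulation = modulation)
  }
  ev <- rbind(
    mk(schedule$cue_onset, schedule$cue_duration, "cue", 1),
    mk(schedule$cue_onset[pos], pred_duration, "prediction_positive",
       stim_traj$v_pos[pos]),
    mk(schedule$cue_onset[neg], pred_duration, "prediction_negative",
       stim_traj$v_neg[neg]),
    mk(schedule$stim_onset[!resist], schedule$stim_duration[!resist],
       "stimulus_no_resistance", 1),
    mk(schedule$stim_onset[resist], schedule$stim_duration[resist],
       "stimulus_resistance", 1),
    mk(schedule$stim_onset[!resist], pe_duration,
       "prediction_error_positive", stim_traj$delta_pos[!resist]),
    mk(schedule$stim_onset[resist], pe_duration,
       "prediction_error_negative", stim_traj$delta_neg[resist]),
    mk(schedule$rating_onset, schedule$rating_duration, "rating", 1)
  )
  ev <- ev[order(match(ev$trial_type, unique(ev$trial_type)), ev$onset), ]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write an event table in BIDS events format
#'
#' Tab-separated with columns onset, duration, trial_type, modulation.
#'
#' @param events An `event_table`.
#' @param path Output file path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select the representative subject of a fitted cohort
#'
#' The subject whose learning rate is closest to the cohort mean; ties are
#' broken by the lowest subject index.
#'
#' @param fits List of `blt_fit` objects (RW fits) for included subjects.
#' @return Integer index into `fits`.
#' @export
select_representative <- function(fits) {
  if (length(fits) == 0) stop("empty cohort")
  alphas <- vapply(fits, function(f) f$theta_map[["alpha"]], numeric(1))
  dist <- abs(alphas - mean(alphas))
  # tolerance guards against float noise so exact ties resolve to the
  # lowest subject index
  which(dist <= min(dist) + 1e-12)[1]
}

#' Validate a prediction trajectory on unseen cohorts
#'
#' Pooled logistic regression of stacked unseen binary prediction decisions
#' on the representative subject's prediction trajectory (plus intercept).
#' A significant positive slope indicates that the trajectory explains
#' decisions it was not fitted to. Perfect separation is reported with a
#' flag alongside a ridge-penalised fallback estimate.
#'
#' @param representative_v Prediction trajectory (length = trials).
#' @param unseen List (or matrix, subjects in rows) of binary decision
#'   series aligned to the same schedule.
#' @return A list with `slope`, `intercept`, `se` (slope SE), `t` (Wald z),
#'   `p`, `n_subjects`, and `separation` flag.
#' @export
validate_unseen <- function(representative_v, unseen) {
  if (is.matrix(unseen)) unseen <- asplit(unseen, 1)
  n_trials <- length(representative_v)
  if (!all(vapply(unseen, length, integer(1)) == n_trials)) {
    stop("all unseen series must have length ", n_trials)
  }
  y <- unlist(unseen, use.names = FALSE)
  assert_binary(y, "unseen decisions")
  x <- rep(representative_v, times = length(unseen))
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 15)
  if (separation) {
    # ridge-penalised fallback: small L2 penalty via one-step augmentation
    aug_y <- c(y, 0, 1, 0, 1)
    aug_x <- c(x, 0, 0, 1, 1)
    w <- c(rep(1, length(y)), rep(0.5, 4))
    fit <- suppressWarnings(stats::glm(aug_y ~ aug_x, weights = w,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    rownames(co) <- c("(Intercept)", "x")
  } else {
    co <- summary(fit)$coefficients
  }
  list(slope = co["x", 1], intercept = co["(Intercept)", 1],
       se = co["x", 2], t = co["x", 3], p = co["x", 4],
       n_subjects = length(unseen), separation = separation)
}
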