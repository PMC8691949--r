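#' Default configuration for a breathing learning task schedule
#'
#' The task pairs two visual cues with a probabilistic inspiratory-resistance
#' outcome. One cue carries an 80% chance of resistance while the other
#' carries the mirrored 20%, and the pairing swaps at every block boundary
#' (4 reversals over 80 trials, with an initial stable period of 30 trials).
#' Block lengths are chosen so that the 80/20 proportions are exactly
#' realizable within every block and resistance is delivered on exactly half
#' of all trials.
#'
#' @param blocks Integer vector of block lengths between reversals.
#' @param p_high Probability of resistance for the currently "high" cue.
#' @param cue_duration Seconds the visual cue (and prediction window) lasts.
#' @param stim_duration Seconds of the resistance/no-resistance period.
#' @param rating_duration Seconds of the post-stimulus difficulty rating.
#'   Not reported in the task description; 4 s is a reconstruction.
#' @param iti_range Two-element range (seconds) of the pseudo-randomized
#'   inter-trial rest period.
#' @return A list understood by [generate_blt_schedule()].
#' @export
blt_schedule_config <- function(blocks = c(30L, 10L, 10L, 10L, 20L),
                                p_high = 0.8,
                                cue_duration = 2.5,
                                stim_duration = 5,
                                rating_duration = 4,
                                iti_range = c(7, 9)) {
  stopifnot(length(p_high) == 1L, p_high > 0.5, p_high < 1,
            length(iti_range) == 2L, iti_range[1] <= iti_range[2])
  list(blocks = as.integer(blocks), p_high = p_high,
       cue_duration = cue_duration, stim_duration = stim_duration,
       rating_duration = rating_duration, iti_range = iti_range)
}

#' Generate a breathing learning task schedule
#'
#' Produces the per-trial cue/outcome sequence and timing of one task
#' session. Within every block each cue appears equally often and the
#' outcome proportions match the block contingency exactly; only the order
#' of trials within a block depends on the seed.
#'
#' @param config Schedule configuration from [blt_schedule_config()].
#' @param seed Integer seed controlling within-block trial order and
#'   inter-trial intervals.
#' @return A `data.frame` of class `blt_schedule` with one row per trial:
#'   `trial`, `block`, `cue` (1/2), `p_resist_cue1` (per-trial contingency),
#'   `outcome` (1 = inspiratory resistance delivered), and timing columns
#'   `cue_onset`, `cue_duration`, `stim_onset`, `stim_duration`,
#'   `rating_onset`, `rating_duration`, `iti`. Reversal trial indices are
#'   stored in `attr(x, "reversals")`.
#' @examples
#' sched <- generate_blt_schedule(seed = 1)
#' nrow(sched)          # 80
#' sum(sched$outcome)   # 40
#' @export
generate_blt_schedule <- function(config = blt_schedule_config(), seed = 1L) {
  blocks <- config$blocks
  p <- config$p_high
  if (any(blocks %% 2L != 0L)) {
    stop("block lengths must be even so both cues appear equally often; ",
         "offending block(s): ", paste(which(blocks %% 2L != 0L), collapse = ", "))
  }
  per_cue <- blocks / 2L
  n_high <- p * per_cue
  if (any(abs(n_high - round(n_high)) > 1e-9)) {
    bad <- which(abs(n_high - round(n_high)) > 1e-9)
    stop(sprintf(
      "contingency %.2f is not exactly realizable within block(s) %s (lengths %s)",
      p, paste(bad, collapse = ", "), paste(blocks[bad], collapse = ", ")))
  }
  n_high <- as.integer(round(n_high))

  seeds <- derive_seeds(seed, length(blocks) + 1L)
  rows <- vector("list", length(blocks))
  # cue 1 starts as the high-probability cue; the pairing swaps each block
  for (b in seq_along(blocks)) {
    high_cue <- if (b %% 2L == 1L) 1L else 2L
    L <- blocks[b]
    half <- per_cue[b]
    # outcomes for the high cue: n_high resistances; low cue mirrored
    cue_vec <- rep(c(high_cue, 3L - high_cue), each = half)
    out_vec <- c(rep(c(1L, 0L), c(n_high[b], half - n_high[b])),
                 rep(c(1L, 0L), c(half - n_high[b], n_high[b])))
    ord <- with_local_seed(seeds[b], sample.int(L))
    rows[[b]] <- data.frame(
      block = b,
      cue = cue_vec[ord],
      outcome = out_vec[ord],
      p_resist_cue1 = if (high_cue == 1L) p else round(1 - p, 12)
    )
  }
  sched <- do.call(rbind, rows)
  n <- nrow(sched)
  sched$trial <- seq_len(n)

  iti <- with_local_seed(seeds[length(seeds)],
                         stats::runif(n, config$iti_range[1], config$iti_range[2]))
  trial_len <- config$cue_duration + config$stim_duration +
    config$rating_duration + iti
  cue_onset <- cumsum(c(0, trial_len[-n]))
  sched$cue_onset <- cue_onset
  sched$cue_duration <- config$cue_duration
  sched$stim_onset <- cue_onset + config$cue_duration
  sched$stim_duration <- config$stim_duration
  sched$rating_onset <- sched$stim_onset + config$stim_duration
  sched$rating_duration <- config$rating_duration
  sched$iti <- iti

  sched <- sched[, c("trial", "block", "cue", "p_resist_cue1", "outcome",
                     "cue_onset", "cue_duration", "stim_onset",
                     "stim_duration", "rating_onset", "rating_duration",
                     "iti")]
  attr(sched, "reversals") <- cumsum(blocks)[-length(blocks)]
  attr(sched, "config") <- config
  attr(sched, "seed") <- seed
  class(sched) <- c("blt_schedule", "data.frame")
  sched
}

#' @export
print.blt_schedule <- function(x, ...) {
  cat(sprintf("Breathing learning task schedule: %d trials, %d reversals (after trials %s)\n",
              nrow(x), length(attr(x, "reversals")),
              paste(attr(x, "reversals"), collapse = ", ")))
  cat(sprintf("resistance on %d/%d trials\n", sum(x$outcome), nrow(x)))
  invisible(x)
}
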