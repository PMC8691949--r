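test_that("stimulus-space transform mirrors by cue", {
  tr <- new_traj(v = c(0.7, 0.7), delta = c(0.3, 0.3))
  st <- to_stimulus_space(tr, cues = c(1, 2))
  expect_equal(st$v_stim, c(0.7, 0.3))
  expect_equal(st$delta_stim, c(0.3, -0.3))
  expect_error(to_stimulus_space(tr, cues = c(1, 2, 1)), "lengths")
})

test_that("valence splits follow the defining equations with the 0.5 rule", {
  sp <- split_certainty(c(0.7, 0.5, 0.2))
  expect_equal(sp$v_pos, c(0.2, 0, 0))
  expect_equal(sp$v_neg, c(0, 0, 0.3))
  pe <- split_prediction_error(c(0.4, 0, -0.8))
  expect_equal(pe$delta_pos, c(0.4, 0, 0))
  expect_equal(pe$delta_neg, c(0, 0, 0.8))
})

test_that("splits are exhaustive, exclusive, and exactly invertible", {
  s <- default_schedule()
  u <- encode_contingency_space(s)
  for (a in c(0.1, 0.45, 0.9)) {
    st <- to_stimulus_space(rw_trajectory(u, a), s$cue)
    expect_true(all(st$v_pos * st$v_neg == 0))
    expect_true(all(st$delta_pos * st$delta_neg == 0))
    expect_equal(st$v_stim, 0.5 + st$v_pos - st$v_neg, tolerance = 1e-12)
    expect_equal(st$delta_stim, st$delta_pos - st$delta_neg,
                 tolerance = 1e-12)
    expect_true(all(st$v_pos >= 0 & st$v_pos <= 0.5))
    expect_true(all(st$delta_pos >= 0 & st$delta_pos <= 1))
  }
})

test_that("event tables carry the contracted regressor structure", {
  s <- default_schedule()
  u <- encode_contingency_space(s)
  st <- to_stimulus_space(rw_trajectory(u, 0.25), s$cue)
  ev <- build_event_table(s, st)
  cnt <- table(ev$trial_type)
  expect_equal(unname(cnt[["cue"]]), 80L)
  expect_equal(unname(cnt[["rating"]]), 80L)
  n_pos <- sum(st$v_stim > 0.5)
  n_neg <- sum(st$v_stim < 0.5)
  n_bound <- sum(st$v_stim == 0.5)
  expect_equal(n_pos + n_neg + n_bound, 80L)
  expect_equal(unname(cnt[["prediction_positive"]]), n_pos)
  expect_equal(unname(cnt[["prediction_negative"]]), n_neg)
  expect_equal(unname(cnt[["stimulus_resistance"]]), 40L)
  expect_equal(unname(cnt[["stimulus_no_resistance"]]), 40L)
  expect_equal(unname(cnt[["prediction_error_positive"]]), 40L)
  expect_equal(unname(cnt[["prediction_error_negative"]]), 40L)
  # zero-magnitude modulations are retained, not dropped
  expect_true(all(ev$modulation >= 0))
  # onsets reproduce the schedule timing
  expect_equal(sort(ev$onset[ev$trial_type == "cue"]), sort(s$cue_onset),
               tolerance = 1e-9)
  expect_equal(sort(ev$onset[ev$trial_type == "stimulus_resistance"]),
               sort(s$stim_onset[s$outcome == 1]), tolerance = 1e-9)
  # onsets non-decreasing within each regressor
  for (tt in names(cnt)) {
    expect_true(all(diff(ev$onset[ev$trial_type == tt]) >= 0))
  }
})

test_that("event tables round-trip through the BIDS events format", {
  s <- default_schedule()
  st <- to_stimulus_space(rw_trajectory(encode_contingency_space(s), 0.25),
                          s$cue)
  ev <- build_event_table(s, st)
  path <- tempfile(fileext = ".tsv")
  write_events_tsv(ev, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(back$onset, ev$onset, tolerance = 1e-9)
  expect_equal(back$trial_type, ev$trial_type)
  unlink(path)
})

test_that("representative selection minimises distance to the mean alpha", {
  mk <- function(a) list(model = "RW", theta_map = c(alpha = a, zeta = 5))
  expect_equal(select_representative(lapply(c(0.1, 0.2, 0.6), mk)), 2L)
  expect_equal(select_representative(lapply(c(0.2, 0.4), mk)), 1L)  # tie
  expect_error(select_representative(list()), "empty")
  set.seed(12)
  alphas <- runif(60)
  fits <- lapply(alphas, mk)
  brute <- which.min(abs(alphas - mean(alphas)))
  expect_equal(select_representative(fits), brute)
})

test_that("trajectory validation detects structure and respects the null", {
  s <- default_schedule()
  u <- encode_contingency_space(s)
  rep_v <- rw_trajectory(u, 0.3)$v
  # null case: coin-flip responders give a near-zero slope and p not small
  set.seed(33)
  pvals <- replicate(40, {
    unseen <- lapply(1:15, function(i) rbinom(80, 1, 0.5))
    validate_unseen(rep_v, unseen)$p
  })
  expect_gt(mean(pvals > 0.05), 0.8)
  # powered case: responders generated from the same trajectory
  hits <- vapply(derive_seeds_for_tests(44, 100), function(sd) {
    unseen <- lapply(seq_len(15), function(i) {
      simulate_agent(s, "RW", 0.3, 5, seed = sd + i)$y
    })
    res <- validate_unseen(rep_v, unseen)
    res$slope > 0 && res$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
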