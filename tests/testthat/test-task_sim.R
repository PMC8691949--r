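test_that("default schedule satisfies all design constants", {
  s <- generate_blt_schedule(seed = 7)
  expect_s3_class(s, "blt_schedule")
  expect_equal(nrow(s), 80L)
  expect_equal(attr(s, "reversals"), c(30L, 40L, 50L, 60L))
  expect_equal(sum(s$outcome), 40L)
  expect_true(all(s$p_resist_cue1 %in% c(0.8, 0.2)))
  # mirrored contingencies and exact within-block proportions per cue
  for (b in unique(s$block)) {
    blk <- s[s$block == b, ]
    expect_equal(sum(blk$cue == 1), sum(blk$cue == 2))
    p1 <- blk$p_resist_cue1[1]
    expect_equal(mean(blk$outcome[blk$cue == 1]), p1)
    expect_equal(mean(blk$outcome[blk$cue == 2]), 1 - p1)
  }
  # contingency alternates across blocks, starting high for cue 1
  expect_equal(unique(s$p_resist_cue1[s$block == 1]), 0.8)
  expect_equal(unique(s$p_resist_cue1[s$block == 2]), 0.2)
})

test_that("block-level counts are invariant to seed; order is not", {
  counts <- function(s) {
    lapply(split(s, s$block), function(b) {
      table(cue = b$cue, outcome = b$outcome)
    })
  }
  s1 <- generate_blt_schedule(seed = 1)
  s2 <- generate_blt_schedule(seed = 2)
  expect_identical(counts(s1), counts(s2))
  expect_false(identical(s1$cue, s2$cue))
  # determinism given seed
  expect_identical(as.data.frame(generate_blt_schedule(seed = 9)),
                   as.data.frame(generate_blt_schedule(seed = 9)))
})

test_that("schedule timing is internally consistent", {
  s <- generate_blt_schedule(seed = 3)
  expect_equal(s$stim_onset, s$cue_onset + s$cue_duration)
  expect_equal(s$rating_onset, s$stim_onset + s$stim_duration)
  expect_true(all(s$iti >= 7 & s$iti <= 9))
  expect_true(all(diff(s$cue_onset) > 0))
})

test_that("unrealizable block configurations raise a named error", {
  cfg <- blt_schedule_config(blocks = c(30, 8, 10, 12, 20))
  expect_error(generate_blt_schedule(cfg), "block")
  cfg_odd <- blt_schedule_config(blocks = c(31, 10, 10, 10, 19))
  expect_error(generate_blt_schedule(cfg_odd), "even")
})

test_that("agent simulation obeys the response-model limits", {
  s <- generate_blt_schedule(seed = 5)
  # noise-free limit: argmax choice wherever the belief is not 0.5
  ag <- simulate_agent(s, "RW", 0.25, 1e6, seed = 1)
  off <- abs(ag$trajectory$v - 0.5) > 1e-6
  expect_true(any(off))
  expect_equal(ag$y[off], as.integer(ag$trajectory$v > 0.5)[off])
  # zeta = 0: pure guessing regardless of beliefs
  ag0 <- simulate_agent(s, "RW", 0.25, 0, seed = 1)
  expect_true(all(ag0$p == 0.5))
  # unknown model errors
  expect_error(simulate_agent(s, "QLearning", 0.2, 5), "unknown model")
  # determinism given seed
  expect_identical(simulate_agent(s, "HGF2", -3, 5, seed = 4)$y,
                   simulate_agent(s, "HGF2", -3, 5, seed = 4)$y)
})

test_that("RW agents at moderate noise perform above chance, below ceiling", {
  s <- default_schedule()
  u <- encode_contingency_space(s)$u
  accs <- vapply(derive_seeds_for_tests(11, 1000), function(sd) {
    mean(simulate_agent(s, "RW", 0.25, 5, seed = sd)$y == u)
  }, numeric(1))
  expect_gt(mean(accs), 0.5)
  expect_lt(mean(accs), 1.0)
})

test_that("empirical choice frequencies match the response model", {
  s <- default_schedule()
  picks <- c(5L, 37L, 77L)
  n_rep <- 10000L
  ys <- vapply(derive_seeds_for_tests(21, n_rep), function(sd) {
    simulate_agent(s, "RW", 0.3, 5, seed = sd)$y[picks]
  }, numeric(length(picks)))
  p_true <- simulate_agent(s, "RW", 0.3, 5, seed = 1)$p[picks]
  for (i in seq_along(picks)) {
    bt <- binom.test(sum(ys[i, ]), n_rep, p_true[i])
    expect_gt(bt$p.value, 0.001)
  }
})

test_that("staircase observers behave sensibly", {
  # ceiling case: near-perfect at one filter settles at the minimum load
  sess <- simulate_fdt_observer(fdt_observer(slope = 50), seed = 1)
  expect_equal(unique(sess$filter_count[sess$phase == "constant"]), 1L)
  expect_error(fdt_observer(slope = 0), "positive")
  # constant phase has the configured number of trials
  sess2 <- simulate_fdt_observer(seed = 2)
  expect_equal(sum(sess2$phase == "constant"), 60L)
  expect_true(all(sess2$confidence >= 1 & sess2$confidence <= 10))
})

test_that("observer accuracy is monotone non-decreasing in filter count", {
  obs <- fdt_observer(slope = 0.4, criterion = 0.1)
  acc <- vapply(1:6, function(f) {
    sess <- simulate_fdt_observer(obs, seed = 100 + f, n_constant = 10000L,
                                  max_search_blocks = 0L, start_filters = f,
                                  adjust_constant = FALSE)
    mean(sess$correct)
  }, numeric(1))
  expect_true(all(diff(acc) >= -0.01))  # small allowance for MC noise
  expect_gt(acc[6], acc[1])
})

test_that("multimodal cohort generator matches its stated world", {
  tab <- generate_multimodal_cohort(seed = 1)
  expect_s3_class(tab, "multimodal_table")
  expect_equal(nrow(tab), 60L)
  expect_equal(table(tab$group), table(factor(rep(c("low", "moderate"),
                                                  each = 30))),
               ignore_attr = TRUE)
  expect_identical(setdiff(names(tab), c("subject_id", "group")),
                   multimodal_measures())
  expect_false(anyNA(tab))
  # zero effects and loadings -> i.i.d. noise
  cfg0 <- multimodal_config(
    group_effects = setNames(numeric(16), multimodal_measures()),
    loadings = matrix(0, 16, 1, dimnames = list(multimodal_measures(), NULL)))
  tab0 <- generate_multimodal_cohort(cfg0, seed = 2)
  X0 <- as.matrix(tab0[, multimodal_measures()])
  expect_lt(max(abs(colMeans(X0))), 0.6)
  expect_true(all(abs(apply(X0, 2, sd) - 1) < 0.4))
  # wrong loadings dimensions error
  bad <- multimodal_config(loadings = matrix(0, 4, 2))
  expect_error(generate_multimodal_cohort(bad), "16 rows")
  # determinism
  expect_identical(generate_multimodal_cohort(seed = 5),
                   generate_multimodal_cohort(seed = 5))
})

test_that("planted group shifts are detected at Bonferroni level", {
  eff <- setNames(numeric(16), multimodal_measures())
  eff[c("STAI_S", "GAD7", "ASI", "CES_D")] <- 1.5
  cfg <- multimodal_config(
    group_effects = eff,
    loadings = matrix(0, 16, 1, dimnames = list(multimodal_measures(), NULL)))
  hits <- vapply(derive_seeds_for_tests(31, 100), function(sd) {
    tab <- generate_multimodal_cohort(cfg, seed = sd)
    res <- compare_groups(tab, c("STAI_S", "GAD7", "ASI", "CES_D"),
                          family_size = 8)
    all(res$significant_corrected)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
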