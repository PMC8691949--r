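# End-to-end study orchestration on synthetic (or user-supplied) cohorts:
# simulate -> fit -> LR-exclude -> BMS -> regressors -> FDT -> multimodal
# statistics, with explicit seeds and delimited-text outputs.

#' Study configuration
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param n_per_group Cohort sizes for the two anxiety groups.
#' @param n_validation Unseen subjects for trajectory validation.
#' @param models Candidate model space.
#' @param schedule_config Schedule configuration
#'   ([blt_schedule_config()]).
#' @param agent_zeta Decision noise of the simulated cohort agents.
#' @param recovery Recovery-study settings (list: `n_subjects`,
#'   `zeta_sim`, `n_iterations`) or `NULL` to skip the stage.
#' @param n_fdt Number of simulated detection observers.
#' @param n_perm PCA permutation count.
#' @param out_dir Output directory for the delimited tables (`NULL` for
#'   no files).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_per_group = c(30L, 30L),
                         n_validation = 15L,
                         models = c("RW", "HGF2", "HGF3"),
                         schedule_config = blt_schedule_config(),
                         agent_zeta = 5,
                         recovery = list(n_subjects = 20L,
                                         zeta_sim = c(1, 5, 10),
                                         n_iterations = 2L),
                         n_fdt = 60L, n_perm = 1000L, out_dir = NULL) {
  structure(list(seed = seed, n_per_group = n_per_group,
                 n_validation = n_validation, models = models,
                 schedule_config = schedule_config, agent_zeta = agent_zeta,
                 recovery = recovery, n_fdt = n_fdt, n_perm = n_perm,
                 out_dir = out_dir),
            class = "study_config")
}

write_study_table <- function(df, path, seed) {
  if (is.null(path)) return(invisible(NULL))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# breathelearn %s; seed=%s",
                     as.character(utils::packageVersion("breathelearn")),
                     seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a study table written by the pipeline
#'
#' @param path CSV path (header comment lines starting with `#` are
#'   skipped).
#' @return A data frame.
#' @export
read_study_table <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a task schedule and a cohort of learning agents, fits every
#' candidate model per subject, excludes subjects whose chosen-model fit
#' does not beat chance (likelihood-ratio test), performs random-effects
#' Bayesian model selection, builds the representative subject's
#' model-based event table, validates the representative trajectory on an
#' unseen cohort, optionally runs the recovery study, simulates and
#' summarises the detection-task observer bank, and computes the
#' multimodal group statistics (comparisons, correlation matrix,
#' permutation PCA, component-score tests). All tables are written as CSV
#' (with a version/seed header) when `config$out_dir` is set.
#'
#' @param config A [study_config()].
#' @return A list of class `study_bundle` with elements `schedule`,
#'   `fits` (per subject x model data frame), `lme_matrix`, `bms`,
#'   `excluded`, `representative`, `events`, `validation`, `recovery`,
#'   `fdt` (per-observer summaries), `cohort`, `questionnaire_stats`,
#'   `fdt_stats`, `correlations`, `pca`, `pc_scores_stats`.
#' @export
run_pipeline <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_seeds(config$seed, 10L)
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  log_msg <- function(...) message(sprintf(...))

  n_subj <- sum(config$n_per_group)
  log_msg("stage simulate: schedule + %d agents", n_subj)
  schedule <- generate_blt_schedule(config$schedule_config, seed = seeds[1])
  u <- encode_contingency_space(schedule)
  agent_seeds <- derive_seeds(seeds[2], 2L * n_subj)
  alphas <- with_local_seed(seeds[3], inv_logit(stats::rnorm(n_subj, 0, 1)))
  agents <- lapply(seq_len(n_subj), function(i) {
    simulate_agent(schedule, "RW", alphas[i], config$agent_zeta,
                   seed = agent_seeds[i])
  })

  log_msg("stage fit: %d subjects x %d models", n_subj,
          length(config$models))
  fit_rows <- list()
  lme <- matrix(NA_real_, n_subj, length(config$models),
                dimnames = list(NULL, config$models))
  rw_fits <- vector("list", n_subj)
  excluded <- logical(n_subj)
  for (i in seq_len(n_subj)) {
    for (m in config$models) {
      f <- fit_map(agents[[i]]$y, u, m,
                   options = fit_options(n_restarts = 5L,
                                         seed = agent_seeds[n_subj + i]))
      if (m == "RW") rw_fits[[i]] <- f
      lme[i, m] <- f$lme
      lr <- if (is.null(f$theta_map)) {
        list(statistic = NA, p = NA, exclude = TRUE)
      } else {
        lr_test_vs_null(f, agents[[i]]$y)
      }
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        subject = i, model = m,
        param = if (is.null(f$theta_map)) NA else unname(f$theta_map[1]),
        zeta = if (is.null(f$theta_map)) NA else f$theta_map[["zeta"]],
        loglik = f$loglik, lme = f$lme, lr_p = lr$p,
        excluded = lr$exclude, converged = f$converged)
      if (m == "RW") excluded[i] <- lr$exclude
    }
  }
  fits <- do.call(rbind, fit_rows)
  rownames(fits) <- NULL
  if (any(excluded)) {
    log_msg("excluding %d subject(s) not beating the chance null",
            sum(excluded))
  }

  log_msg("stage bms")
  bms <- rfx_bms(lme, seed = seeds[4])

  log_msg("stage regressors")
  included <- which(!excluded)
  rep_idx <- included[select_representative(rw_fits[included])]
  rep_fit <- rw_fits[[rep_idx]]
  rep_traj <- rw_trajectory(u, rep_fit$theta_map[["alpha"]])
  stim <- to_stimulus_space(rep_traj, schedule$cue)
  events <- build_event_table(schedule, stim)

  log_msg("stage validate: %d unseen subjects", config$n_validation)
  val_seeds <- derive_seeds(seeds[5], config$n_validation)
  unseen <- lapply(val_seeds, function(s) {
    simulate_agent(schedule, "RW",
                   with_local_seed(s, inv_logit(stats::rnorm(1))),
                   config$agent_zeta, seed = s + 1L)$y
  })
  validation <- validate_unseen(rep_traj$v, unseen)

  recovery <- NULL
  if (!is.null(config$recovery)) {
    log_msg("stage recovery")
    recovery <- run_recovery_study(
      models = config$models, zeta_sim = config$recovery$zeta_sim,
      n_subjects = config$recovery$n_subjects,
      n_iterations = config$recovery$n_iterations, schedule = schedule,
      seed = seeds[6])
  }

  log_msg("stage fdt: %d observers", config$n_fdt)
  sessions <- simulate_fdt_bank(config$n_fdt, seed = seeds[7])
  fdt <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- fdt_summary(sessions[[i]])
    data.frame(subject = i, threshold_filters = s$threshold_filters,
               d_prime = s$d_prime, criterion_c = s$criterion_c,
               mean_confidence = s$mean_confidence, meta_d = s$meta_d,
               m_ratio = s$m_ratio, accuracy = s$accuracy)
  }))

  log_msg("stage stats: multimodal cohort")
  cohort <- generate_multimodal_cohort(
    multimodal_config(n_per_group = config$n_per_group), seed = seeds[8])
  quest <- multimodal_measures()[1:8]
  questionnaire_stats <- compare_groups(cohort, quest, family_size = 8L)
  fdt_meas <- multimodal_measures()[9:12]
  fdt_stats <- compare_groups(cohort, fdt_meas, family_size = 4L)
  correlations <- correlation_matrix(cohort)
  pca <- pca_significance(cohort, n_perm = config$n_perm, seed = seeds[9])
  pc_scores_stats <- if (length(pca$significant)) {
    compare_component_scores(pca, cohort$group)
  } else NULL

  if (!is.null(out)) {
    sd <- config$seed
    write_study_table(as.data.frame(schedule), file.path(out, "schedule.csv"), sd)
    write_study_table(fits, file.path(out, "fits.csv"), sd)
    write_study_table(as.data.frame(lme), file.path(out, "lme.csv"), sd)
    write_study_table(data.frame(model = names(bms$pxp),
                                 expected_freq = bms$expected_freq,
                                 ep = bms$ep, pxp = bms$pxp,
                                 bor = bms$bor, winner = bms$winner),
                      file.path(out, "bms.csv"), sd)
    write_events_tsv(events, file.path(out, "events_representative.tsv"))
    write_study_table(as.data.frame(validation),
                      file.path(out, "validation.csv"), sd)
    if (!is.null(recovery)) {
      write_study_table(recovery$summary, file.path(out, "recovery.csv"), sd)
    }
    write_study_table(fdt, file.path(out, "fdt_summaries.csv"), sd)
    write_study_table(as.data.frame(cohort), file.path(out, "cohort.csv"), sd)
    write_study_table(questionnaire_stats,
                      file.path(out, "questionnaire_stats.csv"), sd)
    write_study_table(fdt_stats, file.path(out, "fdt_stats.csv"), sd)
    write_study_table(as.data.frame(correlations$r),
                      file.path(out, "correlations.csv"), sd)
    write_study_table(data.frame(component = seq_along(pca$var_explained),
                                 var_explained = pca$var_explained,
                                 null_q95 = pca$null_q,
                                 significant = seq_along(pca$var_explained)
                                 %in% pca$significant),
                      file.path(out, "pca.csv"), sd)
    if (!is.null(pc_scores_stats)) {
      write_study_table(pc_scores_stats,
                        file.path(out, "pc_scores_stats.csv"), sd)
    }
  }

  structure(list(schedule = schedule, fits = fits, lme_matrix = lme,
                 bms = bms, excluded = which(excluded),
                 representative = rep_idx, events = events,
                 validation = validation, recovery = recovery, fdt = fdt,
                 cohort = cohort, questionnaire_stats = questionnaire_stats,
                 fdt_stats = fdt_stats, correlations = correlations,
                 pca = pca, pc_scores_stats = pc_scores_stats,
                 config = config),
            class = "study_bundle")
}

#' Read a keyed study configuration file
#'
#' Minimal `key: value` text format (one pair per line, `#` comments,
#' comma-separated lists for vector values). Recognised keys mirror the
#' [study_config()] arguments: `seed`, `n_per_group`, `n_validation`,
#' `agent_zeta`, `n_fdt`, `n_perm`, `out_dir`, `models`.
#'
#' @param path Path to the configuration file.
#' @return A named list of parsed values.
#' @export
read_study_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key: value'): ", ln)
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}

#' Command-line entry point for the pipeline
#'
#' Parses `--seed`, `--out`, cohort/permutation sizes and an optional
#' `--no-recovery` switch, then calls [run_pipeline()]. Invoked by the
#' installed `blt-pipeline` script.
#'
#' @param args Character vector of command-line arguments.
#' @return The `study_bundle`, invisibly.
#' @export
blt_pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("the command-line interface requires the 'optparse' package")
  }
  parser <- optparse::OptionParser(
    usage = "blt-pipeline [options]",
    option_list = list(
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character",
                            default = "blt_output"),
      optparse::make_option("--n-per-group", type = "integer", default = 30L,
                            dest = "n_per_group"),
      optparse::make_option("--n-fdt", type = "integer", default = 60L,
                            dest = "n_fdt"),
      optparse::make_option("--n-perm", type = "integer", default = 1000L,
                            dest = "n_perm"),
      optparse::make_option("--no-recovery", action = "store_true",
                            default = FALSE, dest = "no_recovery"),
      optparse::make_option("--config", type = "character",
                            default = NULL)))
  opt <- optparse::parse_args(parser, args = args)
  if (!is.null(opt$config)) {
    for (kv in names(cf <- read_study_config(opt$config))) {
      opt[[kv]] <- cf[[kv]]
    }
  }
  cfg <- study_config(seed = as.integer(opt$seed),
                      n_per_group = rep(as.integer(opt$n_per_group),
                                        length.out = 2),
                      n_fdt = as.integer(opt$n_fdt),
                      n_perm = as.integer(opt$n_perm),
                      recovery = if (opt$no_recovery) NULL else
                        study_config()$recovery,
                      out_dir = opt$out)
  invisible(run_pipeline(cfg))
}
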