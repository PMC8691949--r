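# Type-1 and type-2 signal detection analysis of the filter detection
# task: perceptual threshold, d', decision bias c, metacognitive bias
# (mean confidence), and metacognitive performance meta-d'/d' (Mratio)
# estimated by per-subject maximum likelihood.

#' Type-1 signal detection indices
#'
#' `d' = z(HR) - z(FAR)` and `c = -(z(HR) + z(FAR)) / 2`. Negative `c`
#' indicates a tendency to report the resistance as present. Degenerate
#' rates (0 or 1) are corrected with the log-linear rule, adding 0.5 to
#' each count and 1 to each denominator, with a warning.
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative counts.
#' @return List with `d_prime`, `criterion_c`, `hit_rate`, `fa_rate`.
#' @export
sdt_indices <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  n_sig <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_sig == 0 || n_noise == 0) stop("need both signal and noise trials")
  hr <- hits / n_sig
  far <- false_alarms / n_noise
  if (hr %in% c(0, 1) || far %in% c(0, 1)) {
    warning("degenerate hit/false-alarm rate; log-linear correction applied")
    hr <- (hits + 0.5) / (n_sig + 1)
    far <- (false_alarms + 0.5) / (n_noise + 1)
  }
  d <- stats::qnorm(hr) - stats::qnorm(far)
  cc <- -(stats::qnorm(hr) + stats::qnorm(far)) / 2
  list(d_prime = d, criterion_c = cc, hit_rate = hr, fa_rate = far)
}

#' Collapse confidence ratings into type-2 response counts
#'
#' Builds the standard rating-count vectors `nR_S1` and `nR_S2` (one entry
#' per response x confidence-bin category, ordered from high-confidence
#' "no" through low-confidence "no" and low-confidence "yes" to
#' high-confidence "yes") from per-trial data. The 1-10 confidence scale is
#' collapsed to `n_bins` bins at fixed edges (default `{1-3, 4-5, 6-7,
#' 8-10}`).
#'
#' @param signal_present,response_yes Binary per-trial vectors.
#' @param confidence Integer ratings 1-10.
#' @param n_bins Number of collapsed confidence bins.
#' @param edges Upper bin edges on the rating scale (length `n_bins`).
#' @return List with `nR_S1`, `nR_S2` (each length `2 * n_bins`) and
#'   `n_bins`.
#' @export
type2_counts <- function(signal_present, response_yes, confidence,
                         n_bins = 4L, edges = c(3, 5, 7, 10)) {
  stopifnot(length(edges) == n_bins, n_bins >= 2L)
  if (any(confidence < 1 | confidence > max(edges))) {
    stop("confidence ratings outside the rating scale")
  }
  bin <- findInterval(confidence, c(-Inf, edges[-n_bins]) + 0.5) # 1..n_bins
  cat_of <- function(yes, b) ifelse(yes == 1, n_bins + b, n_bins + 1 - b)
  categories <- cat_of(response_yes, bin)
  nR_S1 <- tabulate(categories[signal_present == 0], nbins = 2 * n_bins)
  nR_S2 <- tabulate(categories[signal_present == 1], nbins = 2 * n_bins)
  list(nR_S1 = nR_S1, nR_S2 = nR_S2, n_bins = n_bins)
}

#' Maximum-likelihood meta-d' fit
#'
#' Fits metacognitive sensitivity meta-d' under the standard equal-variance
#' type-2 signal detection model: response-conditional rating probabilities
#' are generated by a latent SDT observer with sensitivity meta-d' whose
#' type-1 criterion is held at the relative criterion `c' = c / d'` scaled
#' by `meta_d / d'`. Every rating cell is padded with `1 / (2 * n_bins)`
#' before fitting. Metacognitive efficiency is `Mratio = meta_d / d'`.
#'
#' @param counts Output of [type2_counts()].
#' @return List with `meta_d`, `m_ratio`, `d_prime`, `criterion_c`,
#'   `loglik`, `converged`.
#' @export
fit_meta_d <- function(counts) {
  nb <- counts$n_bins
  pad <- 1 / (2 * nb)
  nR_S1 <- counts$nR_S1 + pad
  nR_S2 <- counts$nR_S2 + pad

  # type-1 indices from the yes/no collapse of the (unpadded) counts
  no_idx <- seq_len(nb)
  yes_idx <- nb + seq_len(nb)
  t1 <- sdt_indices(hits = sum(counts$nR_S2[yes_idx]),
                    misses = sum(counts$nR_S2[no_idx]),
                    false_alarms = sum(counts$nR_S1[yes_idx]),
                    correct_rejections = sum(counts$nR_S1[no_idx]))
  d1 <- t1$d_prime
  c1 <- t1$criterion_c
  if (!is.finite(d1) || abs(d1) < 1e-8) {
    return(list(meta_d = NA_real_, m_ratio = NA_real_, d_prime = d1,
                criterion_c = c1, loglik = NA_real_, converged = FALSE))
  }

  # category probabilities given meta-d and type-2 criteria
  cell_probs <- function(meta_d, t2c_no, t2c_yes) {
    meta_c <- c1 * meta_d / d1
    bounds <- c(-Inf, rev(t2c_no), meta_c, t2c_yes, Inf)
    pr <- function(mu) diff(stats::pnorm(bounds, mean = mu))
    p_s1 <- pr(-meta_d / 2)  # signal absent
    p_s2 <- pr(meta_d / 2)   # signal present
    # ascending evidence intervals already match the category order:
    # leftmost = high-confidence "no" (category 1), rightmost =
    # high-confidence "yes" (category 2 * nb)
    list(s1 = p_s1, s2 = p_s2,
         p_no_s1 = stats::pnorm(meta_c, -meta_d / 2),
         p_no_s2 = stats::pnorm(meta_c, meta_d / 2))
  }
  negll <- function(par) {
    meta_d <- par[1]
    t2c_no <- c1 * meta_d / d1 - cumsum(exp(par[1 + seq_len(nb - 1)]))
    t2c_yes <- c1 * meta_d / d1 + cumsum(exp(par[nb + seq_len(nb - 1)]))
    p <- cell_probs(meta_d, t2c_no, t2c_yes)
    # response-conditional likelihood of the rating counts
    cond <- function(pv, p_no) {
      denom <- c(rep(p_no, nb), rep(1 - p_no, nb))
      pmax(pv / denom, 1e-12)
    }
    ll <- sum(nR_S1 * log(cond(p$s1, p$p_no_s1))) +
      sum(nR_S2 * log(cond(p$s2, p$p_no_s2)))
    if (!is.finite(ll)) 1e10 else -ll
  }

  start <- c(d1, rep(log(0.5), 2 * (nb - 1)))
  res <- tryCatch(stats::optim(start, negll, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  if (is.null(res)) {
    return(list(meta_d = NA_real_, m_ratio = NA_real_, d_prime = d1,
                criterion_c = c1, loglik = NA_real_, converged = FALSE))
  }
  meta_d <- res$par[1]
  list(meta_d = meta_d, m_ratio = meta_d / d1, d_prime = d1,
       criterion_c = c1, loglik = -res$value,
       converged = res$convergence == 0)
}

#' Summarise a filter detection task session
#'
#' Computes the four task measures from the constant-phase trials:
#' perceptual threshold (modal constant-phase filter count), decision bias
#' `c`, metacognitive bias (mean confidence over analysed trials), and
#' metacognitive performance (`Mratio`), together with `d'`.
#'
#' @param session An `fdt_session` (or data frame with the same columns).
#' @param n_bins,edges Confidence-collapsing scheme ([type2_counts()]).
#' @return A list of class `fdt_result` with `threshold_filters`,
#'   `d_prime`, `criterion_c`, `mean_confidence`, `meta_d`, `m_ratio`,
#'   `n_trials`, `accuracy`, `flags`.
#' @export
fdt_summary <- function(session, n_bins = 4L, edges = c(3, 5, 7, 10)) {
  const <- session[session$phase == "constant", ]
  if (nrow(const) == 0) stop("no constant-phase trials in session")
  flags <- character(0)
  drop <- is.na(const$confidence)
  if (any(drop)) {
    flags <- c(flags, sprintf("%d trials dropped (missing confidence)",
                              sum(drop)))
    const <- const[!drop, ]
  }
  tab <- table(const$filter_count)
  threshold <- as.integer(names(tab)[which.max(tab)])
  counts <- type2_counts(const$signal_present, const$response_yes,
                         const$confidence, n_bins, edges)
  t1 <- sdt_indices(sum(const$signal_present & const$response_yes),
                    sum(const$signal_present & !const$response_yes),
                    sum(!const$signal_present & const$response_yes),
                    sum(!const$signal_present & !const$response_yes))
  if (length(unique(const$confidence)) < 2) {
    flags <- c(flags, "degenerate ratings: meta-d' undefined")
    meta <- list(meta_d = NA_real_, m_ratio = NA_real_)
  } else {
    meta <- fit_meta_d(counts)
    if (!isTRUE(meta$converged)) flags <- c(flags, "meta-d' fit did not converge")
  }
  structure(list(threshold_filters = threshold, d_prime = t1$d_prime,
                 criterion_c = t1$criterion_c,
                 mean_confidence = mean(const$confidence),
                 meta_d = meta$meta_d, m_ratio = meta$m_ratio,
                 n_trials = nrow(const), accuracy = mean(const$correct),
                 flags = flags),
            class = "fdt_result")
}

#' @export
print.fdt_result <- function(x, ...) {
  cat(sprintf(paste0("FDT summary: threshold = %d filters, d' = %.2f, ",
                     "c = %.2f,\n  mean confidence = %.2f, meta-d' = %.2f, ",
                     "Mratio = %.2f (accuracy %.2f, %d trials)\n"),
              x$threshold_filters, x$d_prime, x$criterion_c,
              x$mean_confidence, x$meta_d, x$m_ratio, x$accuracy,
              x$n_trials))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
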