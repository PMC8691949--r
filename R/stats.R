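# Normality-gated group comparisons with Bonferroni families, the
# 16-measure correlation matrix with FDR, and the permutation-tested PCA.

#' Anderson-Darling test for composite normality
#'
#' Tests the null hypothesis of normality with estimated mean and variance
#' (the "case 4" setting). The statistic is corrected for sample size as
#' `A* = A^2 (1 + 0.75/n + 2.25/n^2)` and the p value follows the standard
#' piecewise approximation for the normal family.
#'
#' @param x Numeric sample, `n >= 8`.
#' @param alpha Rejection level.
#' @return List with `statistic` (A*), `p`, `reject`.
#' @export
ad_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("Anderson-Darling normality test needs n >= 8")
  if (stats::sd(x) == 0) {
    warning("constant sample: normality rejected by convention")
    return(list(statistic = Inf, p = 0, reject = TRUE))
  }
  z <- sort((x - mean(x)) / stats::sd(x))
  p1 <- stats::pnorm(z, log.p = TRUE)
  p2 <- stats::pnorm(-rev(z), log.p = TRUE)
  A2 <- -n - mean((2 * seq_len(n) - 1) * (p1 + p2))
  Astar <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (Astar >= 0.6) {
    exp(1.2937 - 5.709 * Astar + 0.0186 * Astar^2)
  } else if (Astar >= 0.34) {
    exp(0.9177 - 4.279 * Astar - 1.38 * Astar^2)
  } else if (Astar > 0.2) {
    1 - exp(-8.318 + 42.796 * Astar - 59.938 * Astar^2)
  } else {
    1 - exp(-13.436 + 101.14 * Astar - 223.73 * Astar^2)
  }
  p <- min(max(p, 0), 1)
  list(statistic = Astar, p = p, reject = p < alpha)
}

#' Normality-gated two-group comparisons with a Bonferroni family
#'
#' For each measure, both groups are tested for normality
#' (Anderson-Darling, p < 0.05 rejects); if neither rejects, a two-tailed
#' independent t test is used and the groups are summarised as mean +- SE,
#' otherwise a Wilcoxon rank-sum test with median +- IQR summaries. The
#' Bonferroni-corrected threshold is `0.05 / family_size`.
#'
#' @param table Data frame with a `group` column (two levels) and the
#'   measure columns.
#' @param measures Character vector of measure column names.
#' @param family_size Number of tests in the correction family (defaults
#'   to `length(measures)`).
#' @return A data frame of class `group_comparisons`: one row per measure
#'   with `measure`, `test`, `statistic`, `p`, `family_size`,
#'   `corrected_threshold`, `significant_corrected`,
#'   `significant_uncorrected`, and formatted group summaries.
#' @export
compare_groups <- function(table, measures, family_size = length(measures)) {
  g <- factor(table$group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs at least two observations")
  thr <- 0.05 / family_size
  rows <- lapply(measures, function(m) {
    x <- table[[m]][g == levels(g)[1]]
    y <- table[[m]][g == levels(g)[2]]
    normal <- !ad_normality(x)$reject && !ad_normality(y)$reject
    if (normal) {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      stat <- unname(tt$statistic); p <- tt$p.value
      s1 <- sprintf("%.2f ± %.2f", mean(x), stats::sd(x) / sqrt(length(x)))
      s2 <- sprintf("%.2f ± %.2f", mean(y), stats::sd(y) / sqrt(length(y)))
      test <- "t"
    } else {
      wt <- stats::wilcox.test(x, y, exact = FALSE)
      stat <- unname(wt$statistic); p <- wt$p.value
      s1 <- sprintf("%.2f ± %.2f", stats::median(x), stats::IQR(x))
      s2 <- sprintf("%.2f ± %.2f", stats::median(y), stats::IQR(y))
      test <- "wilcoxon"
    }
    data.frame(measure = m, test = test, statistic = stat, p = p,
               family_size = family_size, corrected_threshold = thr,
               significant_corrected = p < thr,
               significant_uncorrected = p < 0.05,
               summary_group1 = s1, summary_group2 = s2)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- levels(g)
  class(out) <- c("group_comparisons", "data.frame")
  out
}

#' Pairwise correlation matrix with FDR significance tiers
#'
#' Pearson (or Spearman) correlations of all measure pairs with two
#' significance tiers: uncorrected p < 0.05 and Benjamini-Hochberg FDR
#' over the off-diagonal upper triangle.
#'
#' @param table Data frame (e.g. a `multimodal_table`).
#' @param measures Measure column names (default: all 16 cohort measures
#'   present in `table`).
#' @param method `"pearson"` or `"spearman"`.
#' @param fdr_q FDR level.
#' @return List of class `correlation_result`: `r`, `p`, `sig_uncorrected`,
#'   `sig_fdr` (logical matrices), `method`.
#' @export
correlation_matrix <- function(table, measures = NULL, method = "pearson",
                               fdr_q = 0.05) {
  if (is.null(measures)) {
    measures <- intersect(multimodal_measures(), names(table))
  }
  X <- as.matrix(table[, measures])
  if (anyNA(X)) stop("complete cases required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(measures[sds == 0], collapse = ", "))
  }
  m <- length(measures)
  r <- stats::cor(X, method = method)
  p <- matrix(NA_real_, m, m, dimnames = dimnames(r))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ct <- stats::cor.test(X[, i], X[, j], method = method, exact = FALSE)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(p) <- 0
  upper <- upper.tri(p)
  padj <- p
  padj[upper] <- stats::p.adjust(p[upper], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  sig_fdr <- padj < fdr_q
  diag(sig_fdr) <- FALSE
  sig_unc <- p < 0.05
  diag(sig_unc) <- FALSE
  structure(list(r = r, p = p, p_fdr = padj, sig_uncorrected = sig_unc,
                 sig_fdr = sig_fdr, method = method),
            class = "correlation_result")
}

#' Permutation-tested principal component analysis
#'
#' Columns are z-scored, the PCA is computed by singular value
#' decomposition, and a null distribution of variance explained is built by
#' independently permuting every column across subjects and re-running the
#' PCA. Component `k` is significant when its observed variance explained
#' exceeds the 95th percentile of the rank-`k` null distribution. Weights
#' are sign-fixed so the largest-magnitude loading of each component is
#' positive; scores satisfy `t_k(i) = x_i . w_k` exactly.
#'
#' @param table Data frame (e.g. a `multimodal_table`).
#' @param measures Measure columns (default as in [correlation_matrix()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Seed for the permutations.
#' @param level Null-quantile level for significance (default 0.95).
#' @return List of class `pca_result`: `weights` (measures x components),
#'   `scores` (subjects x components), `var_explained` (%), `null_q`
#'   (null quantile per rank, %), `null_dist`, `significant` (indices),
#'   `X` (the z-scored matrix).
#' @export
pca_significance <- function(table, measures = NULL, n_perm = 1000L,
                             seed = 1L, level = 0.95) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (is.null(measures)) {
    measures <- intersect(multimodal_measures(), names(table))
  }
  X <- scale(as.matrix(table[, measures]))
  n <- nrow(X); m <- ncol(X)
  if (m > n) warning("more measures than subjects: rank-deficient PCA")
  varexp <- function(M) {
    d <- svd(M, nu = 0, nv = 0)$d
    ve <- d^2 / sum(d^2)
    ve * 100
  }
  sv <- svd(X)
  ve <- sv$d^2 / sum(sv$d^2) * 100
  W <- sv$v
  # sign convention: dominant loading positive
  for (k in seq_len(ncol(W))) {
    if (W[which.max(abs(W[, k])), k] < 0) W[, k] <- -W[, k]
  }
  scores <- X %*% W
  dimnames(W) <- list(measures, paste0("PC", seq_len(ncol(W))))
  colnames(scores) <- colnames(W)

  perm_seeds <- derive_seeds(seed, n_perm)
  null_dist <- matrix(NA_real_, n_perm, length(ve))
  for (b in seq_len(n_perm)) {
    Xp <- with_local_seed(perm_seeds[b], {
      apply(X, 2, function(col) col[sample.int(n)])
    })
    null_dist[b, ] <- varexp(Xp)
  }
  null_q <- apply(null_dist, 2, stats::quantile, probs = level)
  significant <- which(ve > null_q)
  structure(list(weights = W, scores = scores, var_explained = ve,
                 null_q = null_q, null_dist = null_dist,
                 significant = significant, X = X, level = level),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA with permutation test: %d significant component(s)\n",
              length(x$significant)))
  tab <- rbind(`variance explained (%)` = x$var_explained,
               `null 95th percentile` = x$null_q)
  print(round(tab[, seq_len(min(6, ncol(tab)))], 2))
  invisible(x)
}

#' Group comparisons of significant component scores
#'
#' Normality-gated t / rank-sum tests of the scores of each significant
#' component between the two groups, with Benjamini-Hochberg FDR
#' correction across the significant components.
#'
#' @param pca A `pca_result`.
#' @param groups Group factor aligned with the PCA's subjects.
#' @return A `group_comparisons` data frame with an extra `p_fdr` column.
#' @export
compare_component_scores <- function(pca, groups) {
  if (length(pca$significant) == 0) stop("no significant components")
  sc <- as.data.frame(pca$scores[, pca$significant, drop = FALSE])
  names(sc) <- paste0("PC", pca$significant)
  sc$group <- groups
  out <- compare_groups(sc, setdiff(names(sc), "group"),
                        family_size = length(pca$significant))
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}
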