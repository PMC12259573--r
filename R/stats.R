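#' Bootstrap confidence intervals of scheme differences
#'
#' For each pipeline and each scheme other than the baseline, computes the
#' within-unit accuracy difference (scheme minus baseline), then bootstraps
#' the mean difference by resampling `n_subj` resampling units with
#' replacement over `n_iter` iterations. Units are subject rows pooled
#' across layouts and contrasts (the default), or separate strata if the
#' caller pre-filters the table. The interval is the 2.5/97.5 percentile
#' of the bootstrap distribution.
#'
#' @param acc_table data.frame with columns `subject`, `pipeline`,
#'   `cv_scheme`, `accuracy` and optionally `dataset_layout` / `contrast`
#'   (used to define the resampling unit).
#' @param n_iter bootstrap iterations (default 10000).
#' @param n_subj units drawn per iteration (default 15).
#' @param seed integer seed.
#' @param baseline baseline scheme (default `"pseudo_online"`).
#' @return data.frame with one row per (pipeline, scheme): mean difference
#'   and 95% bounds, of class `ncv_bootstrap_ci`.
#' @export
bootstrap_scheme_differences <- function(acc_table, n_iter = 10000,
                                         n_subj = 15, seed = 1L,
                                         baseline = "pseudo_online") {
  stopifnot(baseline %in% acc_table$cv_scheme)
  unit_cols <- intersect(c("subject", "dataset_layout", "contrast"),
                         names(acc_table))
  acc_table$unit <- do.call(paste, c(acc_table[unit_cols], sep = "|"))
  out <- list()
  with_seed(seed, {
    for (pl in unique(acc_table$pipeline)) {
      sub <- acc_table[acc_table$pipeline == pl, , drop = FALSE]
      wide <- tapply(sub$accuracy, list(sub$unit, sub$cv_scheme), mean)
      if (any(is.na(wide))) stop("missing scheme column for pipeline ", pl)
      schemes <- setdiff(colnames(wide), baseline)
      if (length(schemes) == 0) stop("no scheme column besides the baseline")
      diffs <- wide[, schemes, drop = FALSE] - wide[, baseline]
      n_units <- nrow(diffs)
      draws <- matrix(sample.int(n_units, n_iter * n_subj, replace = TRUE),
                      n_iter, n_subj)
      for (sc in schemes) {
        d <- diffs[, sc]
        boots <- rowMeans(matrix(d[draws], n_iter, n_subj))
        out[[length(out) + 1L]] <- data.frame(
          pipeline = pl, comparison = paste0(sc, " - ", baseline),
          cv_scheme = sc, mean_diff = mean(d),
          lower = unname(quantile(boots, 0.025)),
          upper = unname(quantile(boots, 0.975)),
          n_iterations = n_iter, n_subjects_per_iteration = n_subj,
          stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, out)
  class(res) <- c("ncv_bootstrap_ci", "data.frame")
  res
}

#' Friedman rank test across treatments
#'
#' Non-parametric test for differences among `k` treatments measured on
#' the same `n` subjects; within-subject ranks (mid-ranks for ties), with
#' the chi-squared approximation on `k - 1` degrees of freedom.
#'
#' @param accuracy_matrix subjects x treatments numeric matrix.
#' @return list with `chi2`, `df`, `p`.
#' @export
friedman <- function(accuracy_matrix) {
  m <- as.matrix(accuracy_matrix)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2)
  if (all(apply(m, 1, function(r) max(r) == min(r)))) {
    return(list(chi2 = 0, df = ncol(m) - 1L, p = 1))
  }
  ft <- friedman.test(m)
  list(chi2 = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value)
}

#' Durbin-Conover pairwise post-hoc comparisons
#'
#' Conover's t statistics on the within-subject rank sums,
#' `t = (R_i - R_j) / sqrt(2 n (1 - chi2 / (n (k-1))) *
#' (sum(R^2) - n k (k+1)^2 / 4) / ((n-1)(k-1)))`,
#' with `chi2` the (tie-corrected) Friedman statistic and p-values from
#' the t distribution on `(n-1)(k-1)` degrees of freedom. Signed mean rank
#' differences are reported alongside.
#'
#' @param accuracy_matrix subjects x treatments numeric matrix (columns
#'   named after the treatments).
#' @return data.frame with one row per unordered pair: `t`, raw `p`,
#'   BH-adjusted `p_adj`, `mean_rank_diff` and significance markers.
#' @export
durbin_conover <- function(accuracy_matrix) {
  m <- as.matrix(accuracy_matrix)
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) stop("need at least two treatments")
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(k))
  r <- t(apply(m, 1, rank)) # mid-ranks for ties
  R <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  chi2 <- if (A == C) 0 else friedman(m)$chi2
  df <- (n - 1) * (k - 1)
  denom2 <- 2 * n * (1 - chi2 / (n * (k - 1))) * (A - C) / df
  denom <- sqrt(max(denom2, 0))
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    tval <- if (denom == 0) 0 else (R[i] - R[j]) / denom
    data.frame(treatment_i = colnames(m)[i], treatment_j = colnames(m)[j],
               t = tval, p = 2 * pt(abs(tval), df, lower.tail = FALSE),
               mean_rank_diff = (R[i] - R[j]) / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  adj <- bh_fdr(out$p)
  out$p_adj <- adj$adjusted_pvals
  out$reject <- adj$reject
  out$signif <- significance_marker(out$p_adj)
  rownames(out) <- NULL
  out
}

significance_marker <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (`p * m / i` with monotone enforcement, as in
#' `p.adjust(method = "BH")`) and rejection flags at level `alpha`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `adjusted_pvals` and `reject`.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  list(adjusted_pvals = adj, reject = adj <= alpha)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; the exact null distribution is enumerated
#' for up to 25 non-zero pairs (when there are no rank ties), otherwise
#' the normal approximation with tie correction is used.
#'
#' @param x,y paired numeric vectors.
#' @return list with `W` (signed-rank statistic of `x - y`) and `p`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  nz <- sum(d != 0)
  if (nz == 0) stop("all paired differences are zero")
  if (nz < 5) warning("fewer than 5 non-zero differences; test has little power")
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                     exact = nz <= 25, correct = FALSE))
  list(W = unname(wt$statistic), p = wt$p.value)
}
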