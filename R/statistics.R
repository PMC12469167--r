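#' Pairwise Wilcoxon signed-rank tests between feature sets
#'
#' Two-sided paired Wilcoxon signed-rank test on the matched per-dataset
#' accuracies for every pair of feature sets. Zero differences are discarded
#' (the classical zero-discard convention); the exact null distribution is
#' used for up to 25 non-zero differences without ties, otherwise the normal
#' approximation with continuity correction. A degenerate pair (all
#' differences zero) gets p = 1.
#'
#' @param acc Numeric matrix or data frame, datasets x feature sets, no
#'   missing cells; at least 6 datasets.
#' @return Symmetric matrix of p-values with unit diagonal.
#' @export
wilcoxon_pairwise <- function(acc) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 6) stop("parameter error: need at least 6 datasets")
  if (anyNA(acc)) stop("parameter error: accuracy table has missing cells")
  sets <- colnames(acc)
  if (is.null(sets)) sets <- paste0("set", seq_len(ncol(acc)))
  k <- ncol(acc)
  p <- matrix(1, k, k, dimnames = list(sets, sets))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- acc[, i] - acc[, j]
    d <- d[d != 0]
    if (!length(d)) {
      message("degenerate pair (all differences zero): ", sets[i], " vs ",
              sets[j])
      next
    }
    ties <- any(duplicated(abs(d)))
    use_exact <- length(d) <= 25 && !ties
    pv <- suppressWarnings(
      stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                         exact = use_exact, correct = TRUE))$p.value
    p[i, j] <- p[j, i] <- pv
  }
  p
}

#' Bonferroni-adjusted alpha level
#'
#' `alpha_adj = alpha / n_comparisons`; with the study convention
#' `alpha = 0.01` and 15 pairwise feature-set comparisons this gives
#' about 0.00067.
#'
#' @param alpha Family-wise alpha in (0, 1).
#' @param n_comparisons Number of comparisons (>= 1).
#' @return The adjusted alpha.
#' @export
bonferroni_alpha <- function(alpha, n_comparisons) {
  if (!(alpha > 0 && alpha < 1)) stop("parameter error: alpha must be in (0,1)")
  if (n_comparisons < 1) stop("parameter error: n_comparisons must be >= 1")
  alpha / n_comparisons
}

#' Significance matrix at an adjusted alpha
#'
#' Entry is `TRUE` iff `p < alpha_adj` (strict inequality); the diagonal is
#' `FALSE`.
#'
#' @param p Symmetric p-value matrix.
#' @param alpha_adj Adjusted alpha level.
#' @return Logical matrix of the same shape.
#' @export
significance_table <- function(p, alpha_adj) {
  sig <- p < alpha_adj
  diag(sig) <- FALSE
  sig
}
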