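# Two-sample tests applied along principal components of the isoform
# ratio space.

#' Welch two-sample t-test p-value
#'
#' Two-sided Welch t-test (unequal variances, Welch-Satterthwaite
#' degrees of freedom). Degenerate inputs where both groups are constant
#' return p = 1 when the means agree and a machine-epsilon sentinel when
#' they differ.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return two-sided p-value.
#' @export
welch_t_pvalue <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t_pvalue needs >= 2 observations per group")
  if (var(x) == 0 && var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else .Machine$double.eps)
  }
  t.test(x, y, var.equal = FALSE)$p.value
}

#' General independence test p-value (two-sample continuous case)
#'
#' Permutation-based general independence test for a continuous response
#' against a two-level grouping, using the asymptotic normal reference.
#' The linear statistic is the sum of the first group's values; its
#' conditional mean and variance under random relabeling have closed
#' forms, giving a Z score and a two-sided normal p-value. This is the
#' two-sample special case of the conditional-inference framework.
#'
#' @param x,y numeric vectors (lengths >= 1, pooled length >= 3).
#' @return two-sided p-value.
#' @export
independence_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx < 1 || ny < 1 || n < 3)
    stop("independence_pvalue needs both groups non-empty, pooled n >= 3")
  v <- c(x, y)
  vbar <- mean(v)
  ssq <- sum((v - vbar)^2) / n
  if (ssq == 0) return(1)
  tstat <- sum(x)
  mu <- nx * vbar
  sig2 <- nx * ny / (n - 1) * ssq
  z <- (tstat - mu) / sqrt(sig2)
  2 * pnorm(-abs(z))
}

#' Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the pooled sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and
#' continuity corrections. All-tied data return p = 1 (two-sided).
#'
#' @param x,y numeric vectors, non-empty.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return p-value.
#' @export
rank_sum_pvalue <- function(x, y,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y))
    stop("rank_sum_pvalue needs both groups non-empty")
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  if (ties && length(unique(pooled)) == 1L) return(1)
  exact <- (length(pooled) <= 12) && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)$p.value)
  if (is.nan(p)) 1 else min(p, 1)
}
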