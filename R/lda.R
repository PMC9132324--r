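# Isoform ratio vectors and the LDA permutation model.

#' Per-sample isoform ratio vectors for one gene
#'
#' Collects the gene's isoform abundances into one vector per sample and
#' normalizes each to sum to 1. Samples with zero counts across all of
#' the gene's isoforms carry no ratio information and are dropped
#' (recorded in `dropped_samples`).
#'
#' @param counts an [isoform_counts] object.
#' @param gene gene id with at least 2 isoforms in the matrix.
#' @return a `ratio_matrix`: list with `gene_id`, `isoform_ids`,
#'   `sample_ids`, `proportions` (samples x isoforms, rows sum to 1) and
#'   `dropped_samples`.
#' @export
normalize_isoform_vectors <- function(counts, gene) {
  iso <- gene_isoforms(counts, gene)
  if (length(iso) == 0)
    stop("gene '", gene, "' not testable: absent from matrix")
  if (length(iso) < 2)
    stop("gene '", gene, "' not testable: single isoform")
  raw <- t(counts$values[iso, , drop = FALSE])  # samples x isoforms
  totals <- rowSums(raw)
  keep <- totals > 0
  props <- raw[keep, , drop = FALSE] / totals[keep]
  structure(list(gene_id = gene,
                 isoform_ids = iso,
                 sample_ids = rownames(props),
                 proportions = props,
                 dropped_samples = rownames(raw)[!keep]),
            class = "ratio_matrix")
}

# Reduce the proportion matrix to a full-dimensional coordinate set by
# dropping the coordinate with the smallest overall variance (the
# sum-to-1 constraint removes one degree of freedom; which coordinate is
# dropped does not change the projection space).
reduce_ratio_coords <- function(props) {
  v <- apply(props, 2, var)
  props[, -which.min(v), drop = FALSE]
}

group_indicator <- function(ratios, groups) {
  g <- groups[ratios$sample_ids]
  if (any(is.na(g)))
    stop("group labels missing for samples: ",
         paste(head(ratios$sample_ids[is.na(g)], 3), collapse = ", "))
  lev <- unique(g)
  if (length(lev) != 2) stop("exactly two groups required")
  list(ind = as.integer(g == lev[2L]), levels = lev)
}

#' Project isoform ratio vectors onto the best-separating axis
#'
#' Fisher linear discriminant between the two sample groups, computed on
#' the reduced ratio coordinates (see Details). The pooled within-group
#' covariance is pseudo-inverted, so genes with more isoforms than
#' samples remain projectable. The separation statistic is
#' \deqn{(\mu_a - \mu_b)^2 / (\sigma^2_a + \sigma^2_b)}
#' on the projections, with unbiased group variances.
#'
#' When both projected group variances are zero the statistic is 0 for
#' equal means and `Inf` for unequal means.
#'
#' @param ratios a `ratio_matrix` from [normalize_isoform_vectors].
#' @param groups named vector (sample id -> group label, two levels).
#' @return list with `projections` (named per-sample scalars), `summary`
#'   (list `mu_a`, `mu_b`, `var_a`, `var_b`, `statistic`, `groups`).
#' @export
lda_project <- function(ratios, groups) {
  gi <- group_indicator(ratios, groups)
  if (min(tabulate(gi$ind + 1L, 2L)) < 2)
    stop("insufficient group size: both groups need >= 2 samples")
  X <- reduce_ratio_coords(ratios$proportions)
  i1 <- gi$ind == 0L
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[!i1, , drop = FALSE])
  c1 <- sweep(X[i1, , drop = FALSE], 2, m1)
  c2 <- sweep(X[!i1, , drop = FALSE], 2, m2)
  sw <- (crossprod(c1) + crossprod(c2)) / (nrow(X) - 2)
  d <- m1 - m2
  w <- if (sum(abs(sw)) < 1e-300) d else drop(MASS::ginv(sw) %*% d)
  if (sum(abs(w)) < 1e-300) w <- d
  proj <- drop(X %*% w)
  names(proj) <- ratios$sample_ids
  mu_a <- mean(proj[i1]); mu_b <- mean(proj[!i1])
  var_a <- var(proj[i1]); var_b <- var(proj[!i1])
  denom <- var_a + var_b
  statistic <- if (denom <= 0) {
    if (mu_a == mu_b) 0 else Inf
  } else (mu_a - mu_b)^2 / denom
  list(projections = proj,
       summary = list(mu_a = mu_a, mu_b = mu_b, var_a = var_a,
                      var_b = var_b, statistic = statistic,
                      groups = gi$levels))
}

#' Permutation test on the LDA separation statistic
#'
#' Recomputes the full discriminant fit (direction and statistic) under
#' random relabelings of the samples. The p-value is
#' `(1 + b) / (n_iter + 1)` where `b` counts permuted statistics at least
#' as large as the observed one, so the smallest attainable p is
#' `1 / (n_iter + 1)`. When the number of distinct labelings is at most
#' `n_iter` (and `method = "auto"`), all labelings are enumerated instead
#' and the p-value is exact.
#'
#' @param ratios a `ratio_matrix` from [normalize_isoform_vectors].
#' @param groups named vector (sample id -> group label, two levels).
#' @param n_iter number of random relabelings (default 10000).
#' @param seed optional integer seed for the relabelings.
#' @param method `"auto"` (exhaustive when feasible), `"sampled"` or
#'   `"exhaustive"`.
#' @return list with `p`, `statistic`, `method` (`"exhaustive"` or
#'   `"sampled"`), and `n_labelings` (number of enumerated or sampled
#'   relabelings).
#' @export
lda_permutation_test <- function(ratios, groups, n_iter = 10000L,
                                 seed = NULL,
                                 method = c("auto", "sampled",
                                            "exhaustive")) {
  method <- match.arg(method)
  if (n_iter < 1) stop("n_iter must be >= 1")
  gi <- group_indicator(ratios, groups)
  n <- length(gi$ind)
  n1 <- sum(gi$ind == 0L)
  if (min(n1, n - n1) < 2)
    stop("insufficient group size: both groups need >= 2 samples")
  X <- reduce_ratio_coords(ratios$proportions)
  obs <- lda_stat_cpp(X, gi$ind)

  m_total <- choose(n, n1)
  exhaustive <- switch(method,
                       auto = is.finite(m_total) && m_total <= n_iter,
                       exhaustive = TRUE,
                       sampled = FALSE)
  if (exhaustive) {
    if (!is.finite(m_total) || m_total > 5e6)
      stop("exhaustive enumeration infeasible for ", n, " samples")
    combos <- combn(n, n1)
    perms <- matrix(1L, n, ncol(combos))
    perms[cbind(as.vector(combos),
                rep(seq_len(ncol(combos)), each = n1))] <- 0L
    stats <- lda_perm_stats_cpp(X, perms)
    p <- sum(stats >= obs) / m_total
    return(list(p = p, statistic = obs, method = "exhaustive",
                n_labelings = m_total))
  }
  if (!is.null(seed)) set.seed(seed)
  perms <- replicate(n_iter, sample(gi$ind))
  stats <- lda_perm_stats_cpp(X, perms)
  p <- (1 + sum(stats >= obs)) / (n_iter + 1)
  list(p = p, statistic = obs, method = "sampled", n_labelings = n_iter)
}

#' Principal components of the isoform ratio space
#'
#' PCA of the per-sample ratio vectors, centered on the overall mean and
#' unscaled. Components with variance at most `1e-12` times the leading
#' variance are dropped; the sum-to-1 constraint forces at least one
#' such component, so a gene with n isoforms retains at most n - 1
#' components. Identical vectors across all samples retain zero
#' components.
#'
#' @param ratios a `ratio_matrix` from [normalize_isoform_vectors].
#' @return list with `coordinates` (samples x retained components),
#'   `variances` (per retained component) and `n_components`.
#' @export
pca_components <- function(ratios) {
  if (nrow(ratios$proportions) < 2)
    stop("pca_components needs >= 2 samples")
  pc <- prcomp(ratios$proportions, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  keep <- v > 1e-12 * v[1L]
  if (v[1L] <= 0) keep <- rep(FALSE, length(v))
  list(coordinates = pc$x[, keep, drop = FALSE],
       variances = v[keep],
       n_components = sum(keep))
}
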