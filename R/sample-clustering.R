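# Per-metastatic-sample alteration calling against the primary pool,
# ternary digitization, recurrence filtering, elbow k-means
# biclustering, and cluster-metadata enrichment.

#' Quasi-Poisson test of one metastatic sample against the primary pool
#'
#' Fits a quasi-Poisson GLM (log link) of the abundances on a
#' metastatic-vs-primary indicator, with the single metastatic
#' observation as one group. The two-group model is saturated, so the
#' fit has closed form: fitted means are the group means, the Pearson
#' dispersion is X^2 / (N - 2), and the indicator coefficient gets a
#' Wald t-test on N - 2 degrees of freedom (two-sided). TPM-scale
#' (non-integer) responses are valid under quasi-likelihood. Fitted
#' group means of zero sit on the boundary of the log-link parameter
#' space and are floored at 0.5 (half a count), which keeps the
#' coefficient and its standard error finite.
#'
#' @param primary_values non-negative abundances, length >= 3.
#' @param metastatic_value single non-negative abundance.
#' @return list with `coefficient` (log ratio metastatic/primary),
#'   `sign` (-1/0/+1), `p` (two-sided), `dispersion`.
#' @examples
#' per_sample_glm_test(c(1, 3, 2, 2), 8)  # p ~ 0.017, sign +1
#' @export
per_sample_glm_test <- function(primary_values, metastatic_value) {
  n1 <- length(primary_values)
  if (n1 < 3) stop("need >= 3 primary values")
  if (any(primary_values < 0) || metastatic_value < 0)
    stop("abundances must be non-negative")
  mu_floor <- 0.5
  mu1 <- mean(primary_values)
  y2 <- metastatic_value
  if (mu1 == 0 && y2 == 0)
    return(list(coefficient = 0, sign = 0L, p = 1, dispersion = 1))
  mu1_eff <- max(mu1, mu_floor * (mu1 == 0))
  if (mu1 == 0) mu1_eff <- mu_floor
  mu2_eff <- if (y2 == 0) mu_floor else y2
  x2 <- if (mu1 > 0) sum((primary_values - mu1)^2 / mu1) else 0
  x2 <- x2 + (y2 - mu2_eff)^2 / mu2_eff  # 0 except on the boundary
  df <- n1 + 1 - 2
  phi <- if (x2 == 0) 1 else x2 / df
  coefficient <- log(mu2_eff / mu1_eff)
  se <- sqrt(phi * (1 / (n1 * mu1_eff) + 1 / mu2_eff))
  tval <- coefficient / se
  p <- 2 * pt(-abs(tval), df)
  list(coefficient = coefficient, sign = as.integer(sign(coefficient)),
       p = min(max(p, .Machine$double.eps), 1), dispersion = phi)
}

#' Per-sample alteration calls for all isoforms
#'
#' Vectorized application of [per_sample_glm_test]: every isoform of
#' every metastatic sample is tested against the primary pool, yielding
#' matrices of p-values and coefficient signs (isoforms x metastatic
#' samples).
#'
#' @param counts an [isoform_counts] object.
#' @param meta metadata data.frame covering the samples of `counts`.
#' @param isoforms isoform ids to test (default: all).
#' @return list with matrices `p` and `sign`, and vector `dispersion`
#'   (per isoform, from the primary pool).
#' @export
per_sample_calls <- function(counts, meta, isoforms = NULL) {
  if (is.null(isoforms)) isoforms <- rownames(counts$values)
  pri_ids <- meta$sample_id[meta$sample_type == "primary"]
  met_ids <- meta$sample_id[meta$sample_type == "metastatic"]
  if (length(pri_ids) < 3) stop("need >= 3 primary samples")
  mu_floor <- 0.5
  P <- counts$values[isoforms, pri_ids, drop = FALSE]
  M <- counts$values[isoforms, met_ids, drop = FALSE]
  n1 <- length(pri_ids)
  df <- n1 - 1
  mu1 <- rowMeans(P)
  x2_pri <- rowSums((P - mu1)^2 / ifelse(mu1 > 0, mu1, 1)) * (mu1 > 0)
  mu1_eff <- ifelse(mu1 > 0, mu1, mu_floor)
  mu2_eff <- ifelse(M > 0, M, mu_floor)
  x2 <- x2_pri + (M - mu2_eff)^2 / mu2_eff
  phi <- ifelse(x2 == 0, 1, x2 / df)
  coef <- log(mu2_eff / mu1_eff)
  se <- sqrt(phi * (1 / (n1 * mu1_eff) + 1 / mu2_eff))
  p <- 2 * pt(-abs(coef / se), df)
  p <- pmin(pmax(p, .Machine$double.eps), 1)
  sgn <- sign(coef)
  both_zero <- (mu1 == 0) & (M == 0)
  p[both_zero] <- 1
  sgn[both_zero] <- 0
  dimnames(p) <- dimnames(sgn) <- list(isoforms, met_ids)
  list(p = p, sign = sgn,
       dispersion = setNames(ifelse(x2_pri == 0, 1, x2_pri / df),
                             isoforms))
}

#' Ternary digitization of a per-sample call
#'
#' Direction-aware thresholding: +1 for significant increases
#' (p < `up_threshold`), -1 for decreases at the more liberal
#' p < `down_threshold` (low-count Poisson-like data rarely reach strong
#' significance in the downward direction), 0 otherwise.
#'
#' @param p p-value(s) in (0, 1].
#' @param sign coefficient sign(s), -1/0/+1.
#' @param up_threshold p cutoff for +1 calls (default 0.05).
#' @param down_threshold p cutoff for -1 calls (default 0.20).
#' @return entries in \{-1, 0, +1\}, same shape as `p`.
#' @export
digitize <- function(p, sign, up_threshold = 0.05, down_threshold = 0.20) {
  stopifnot(up_threshold > 0, up_threshold < 1,
            down_threshold > 0, down_threshold < 1)
  out <- (sign > 0 & p < up_threshold) - (sign < 0 & p < down_threshold)
  out[] <- as.integer(out)
  out
}

#' Restrict a digitized matrix to recurrently altered isoforms
#'
#' Keeps an isoform iff it is altered (nonzero entry) in strictly more
#' than `min_fraction` of the samples.
#'
#' @param d digitized matrix (isoforms x samples, entries -1/0/+1).
#' @param min_fraction recurrence threshold in (0, 1) applied strictly;
#'   0 keeps every isoform with at least one alteration.
#' @return the row-filtered matrix.
#' @export
filter_recurrent <- function(d, min_fraction = 0.13) {
  stopifnot(min_fraction >= 0, min_fraction < 1)
  altered <- rowSums(d != 0)
  d[altered > min_fraction * ncol(d), , drop = FALSE]
}

#' K-means with elbow-selected cluster count
#'
#' Runs Euclidean k-means (10 restarts per k) over `k_range` and picks
#' the number of clusters at the elbow of the within-cluster
#' sum-of-squares curve, operationalized as the largest second
#' difference of the curve. `k_override` substitutes a manual choice
#' while still returning the curve for inspection. A degenerate matrix
#' (all items identical) yields k = 1.
#'
#' @param m numeric matrix.
#' @param axis cluster `"rows"` or `"columns"`.
#' @param k_range candidate cluster counts.
#' @param seed integer seed (restarts are stochastic).
#' @param k_override optional manual k.
#' @param nstart restarts per k.
#' @return list with `cluster` (named assignments), `k`, `wss_curve`
#'   (named by k) and `seed`.
#' @export
elbow_kmeans <- function(m, axis = c("rows", "columns"), k_range = 1:10,
                         seed = 1L, k_override = NULL, nstart = 10L) {
  axis <- match.arg(axis)
  if (axis == "columns") m <- t(m)
  n_distinct <- nrow(unique(m))
  k_range <- k_range[k_range >= 1 & k_range <= n_distinct]
  if (!length(k_range)) k_range <- 1L
  set.seed(seed)
  fits <- lapply(k_range, function(k)
    kmeans(m, centers = k, nstart = nstart, iter.max = 50L))
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  names(wss) <- k_range
  k <- if (!is.null(k_override)) {
    as.integer(k_override)
  } else if (length(k_range) < 3) {
    k_range[1L]
  } else {
    d2 <- wss[-c(length(wss) - 1, length(wss))] -
      2 * wss[-c(1, length(wss))] + wss[-(1:2)]
    k_range[which.max(d2) + 1L]
  }
  fit <- if (k %in% k_range) fits[[match(k, k_range)]] else {
    set.seed(seed)
    kmeans(m, centers = min(k, n_distinct), nstart = nstart,
           iter.max = 50L)
  }
  list(cluster = setNames(fit$cluster, rownames(m)), k = k,
       wss_curve = wss, seed = seed)
}

#' Enrichment of metadata labels within sample clusters
#'
#' For every (cluster, label level) pair, builds the 2x2 table
#' in-cluster vs out-of-cluster against label vs not-label and tests
#' enrichment with a one-sided Fisher exact test. The odds ratio is the
#' sample odds ratio from the raw cells, with 0.5 added to every cell
#' only when some cell is zero. Samples with a missing label are
#' dropped.
#'
#' @param assignment named vector, sample id -> cluster label.
#' @param labels named vector, sample id -> categorical metadata level.
#' @return data.frame with columns `cluster`, `level`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `p`.
#' @export
cluster_enrichment <- function(assignment, labels) {
  labels <- labels[names(assignment)]
  ok <- !is.na(labels)
  assignment <- assignment[ok]; labels <- labels[ok]
  rows <- list()
  for (cl in sort(unique(assignment))) {
    in_cl <- assignment == cl
    if (!sum(in_cl)) next
    for (lv in sort(unique(labels))) {
      has <- labels == lv
      a <- sum(in_cl & has); b <- sum(in_cl & !has)
      cc <- sum(!in_cl & has); d <- sum(!in_cl & !has)
      p <- fisher.test(matrix(c(a, cc, b, d), 2),
                       alternative = "greater")$p.value
      cells <- c(a, b, cc, d)
      if (any(cells == 0)) cells <- cells + 0.5
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, level = lv, a = a, b = b, c = cc, d = d,
        odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify samples as immune-infiltrate by 2-center k-means
#'
#' Clusters the samples with k = 2 on their digitized profiles
#' restricted to an immune isoform program; the cluster with the higher
#' rate of up (+1) calls over the program is labeled `"infiltrate"`.
#'
#' @param d digitized matrix (isoforms x samples).
#' @param immune_isoforms isoform ids forming the immune program; must
#'   intersect the rows of `d`.
#' @param seed integer seed.
#' @return named character vector, sample id -> `"infiltrate"` or
#'   `"other"`.
#' @export
classify_infiltrate <- function(d, immune_isoforms, seed = 1L) {
  rows <- intersect(immune_isoforms, rownames(d))
  if (!length(rows)) stop("immune isoform group absent from the matrix")
  sub <- d[rows, , drop = FALSE]
  if (all(sub == 0)) {
    warning("immune program rows are all zero; labeling every sample 'other'")
    return(setNames(rep("other", ncol(d)), colnames(d)))
  }
  set.seed(seed)
  fit <- kmeans(t(sub), centers = 2, nstart = 10L)
  up_rate <- vapply(1:2, function(k)
    mean(sub[, fit$cluster == k, drop = FALSE] == 1), numeric(1))
  lab <- ifelse(fit$cluster == which.max(up_rate), "infiltrate", "other")
  setNames(lab, colnames(d))
}

#' End-to-end biclustering of metastatic samples
#'
#' Pipeline wrapper: per-sample quasi-Poisson calls, ternary
#' digitization, recurrence filtering, then elbow k-means on both axes
#' (samples and isoforms).
#'
#' @param counts an [isoform_counts] object.
#' @param meta metadata data.frame.
#' @param up_threshold,down_threshold digitization cutoffs (see
#'   [digitize]).
#' @param min_fraction recurrence threshold (see [filter_recurrent]).
#' @param k_samples,k_isoforms manual cluster counts, or `NULL` for the
#'   elbow rule.
#' @param k_range candidate cluster counts for the elbow search.
#' @param seed integer seed.
#' @return list with `digitized` (filtered ternary matrix),
#'   `sample_clusters`, `isoform_groups` (both [elbow_kmeans] results)
#'   and `calls` (the raw call matrices).
#' @export
cluster_metastatic_samples <- function(counts, meta, up_threshold = 0.05,
                                       down_threshold = 0.20,
                                       min_fraction = 0.13,
                                       k_samples = NULL, k_isoforms = NULL,
                                       k_range = 1:8, seed = 1L) {
  calls <- per_sample_calls(counts, meta)
  dig <- digitize(calls$p, calls$sign, up_threshold, down_threshold)
  dig <- filter_recurrent(dig, min_fraction)
  if (!nrow(dig)) stop("no recurrently altered isoforms at this threshold")
  list(digitized = dig,
       sample_clusters = elbow_kmeans(dig, axis = "columns",
                                      k_range = k_range, seed = seed,
                                      k_override = k_samples),
       isoform_groups = elbow_kmeans(dig, axis = "rows",
                                     k_range = k_range, seed = seed + 1L,
                                     k_override = k_isoforms),
       calls = calls)
}
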