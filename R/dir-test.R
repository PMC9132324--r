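# Gene-level DIR testing: the permutation model and the PCA-combined
# model family, plus the test-comparison harness.

#' Test one gene for differential isoform ratios
#'
#' Runs the full per-gene DIR pipeline: normalize the isoform vectors,
#' optionally run the LDA permutation test, then the PCA model — Welch
#' t-test and general independence test along each retained principal
#' component, each family combined with Fisher's method, and the two
#' family p-values merged by their geometric mean (`p_geo`). Genes that
#' cannot be tested (single isoform, too few samples per group, no
#' ratio variance) yield missing p-values with a `reason` code instead
#' of an error.
#'
#' @param counts an [isoform_counts] object.
#' @param meta metadata data.frame covering the samples of `counts`.
#' @param gene gene id.
#' @param n_iter permutation count for the LDA model (default 10000).
#' @param seed optional integer seed for the permutations.
#' @param run_permutation run the (slower) LDA permutation model too?
#' @param group_col metadata column holding the two group labels.
#' @param group_a,group_b the two group levels (reference first).
#' @return one-row data.frame with columns `gene_id`, `n_isoforms`,
#'   `n_samples_a`, `n_samples_b`, `n_components`, `p_perm`,
#'   `p_t_fisher`, `p_coin_fisher`, `p_geo`, `reason`.
#' @export
dir_test_gene <- function(counts, meta, gene, n_iter = 10000L, seed = NULL,
                          run_permutation = FALSE,
                          group_col = "sample_type",
                          group_a = "primary", group_b = "metastatic") {
  res <- data.frame(gene_id = gene, n_isoforms = NA_integer_,
                    n_samples_a = NA_integer_, n_samples_b = NA_integer_,
                    n_components = NA_integer_, p_perm = NA_real_,
                    p_t_fisher = NA_real_, p_coin_fisher = NA_real_,
                    p_geo = NA_real_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  n_iso <- length(gene_isoforms(counts, gene))
  res$n_isoforms <- n_iso
  if (n_iso == 0) { res$reason <- "absent"; return(res) }
  if (n_iso < 2) { res$reason <- "single_isoform"; return(res) }

  ratios <- normalize_isoform_vectors(counts, gene)
  groups <- setNames(meta[[group_col]], meta$sample_id)
  groups <- groups[groups %in% c(group_a, group_b)]
  ratios <- subset_ratio_samples(ratios,
                                 intersect(ratios$sample_ids, names(groups)))
  g <- groups[ratios$sample_ids]
  na <- sum(g == group_a); nb <- sum(g == group_b)
  res$n_samples_a <- na; res$n_samples_b <- nb
  if (na < 2 || nb < 2) { res$reason <- "insufficient_samples"; return(res) }
  # fix level order so group_a is the reference
  g <- factor(g, levels = c(group_a, group_b))
  gnamed <- setNames(as.character(g), ratios$sample_ids)

  if (run_permutation) {
    perm <- lda_permutation_test(ratios, gnamed, n_iter = n_iter,
                                 seed = seed)
    res$p_perm <- perm$p
  }

  pcs <- pca_components(ratios)
  res$n_components <- pcs$n_components
  if (pcs$n_components == 0) { res$reason <- "no_variance"; return(res) }

  is_a <- g == group_a
  p_t <- p_coin <- numeric(pcs$n_components)
  for (k in seq_len(pcs$n_components)) {
    xa <- pcs$coordinates[is_a, k]
    xb <- pcs$coordinates[!is_a, k]
    p_t[k] <- welch_t_pvalue(xa, xb)
    p_coin[k] <- independence_pvalue(xa, xb)
  }
  res$p_t_fisher <- fisher_combine(p_t)
  res$p_coin_fisher <- fisher_combine(p_coin)
  res$p_geo <- geometric_combine(res$p_t_fisher, res$p_coin_fisher)
  res
}

subset_ratio_samples <- function(ratios, sample_ids) {
  keep <- ratios$sample_ids %in% sample_ids
  ratios$proportions <- ratios$proportions[keep, , drop = FALSE]
  ratios$sample_ids <- ratios$sample_ids[keep]
  ratios
}

#' Test all genes for differential isoform ratios
#'
#' Applies [dir_test_gene] to every gene (or a supplied subset) and
#' appends Benjamini-Hochberg adjusted p-values: `p_adj` for the
#' geometric-mean model and, when the permutation model was run,
#' `p_perm_adj`.
#'
#' @inheritParams dir_test_gene
#' @param genes gene ids to test; default all genes in the matrix.
#' @param ... passed on to [dir_test_gene].
#' @return data.frame, one row per gene, [dir_test_gene] columns plus
#'   `p_adj` and `p_perm_adj`.
#' @export
dir_test <- function(counts, meta, genes = NULL, n_iter = 10000L,
                     seed = NULL, run_permutation = FALSE, ...) {
  if (is.null(genes)) genes <- unique(counts$gene_of)
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    gene_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    rows[[i]] <- dir_test_gene(counts, meta, genes[i], n_iter = n_iter,
                               seed = gene_seed,
                               run_permutation = run_permutation, ...)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_geo)
  out$p_perm_adj <- bh_adjust(out$p_perm)
  out
}

#' Youden's J for one candidate test against a reference
#'
#' Treats reference p-values below `alpha` as ground-truth positives and
#' candidate p-values below `alpha` as calls;
#' J = sensitivity + specificity - 1.
#'
#' @param candidate,reference numeric p-value vectors, same genes.
#' @param alpha significance level.
#' @return J in \[-1, 1\], or `NA` when the reference has no positives
#'   or no negatives at `alpha`.
#' @export
youden_j <- function(candidate, reference, alpha) {
  pos <- reference < alpha
  call <- candidate < alpha
  if (!any(pos) || all(pos)) return(NA_real_)
  sens <- sum(call & pos) / sum(pos)
  spec <- sum(!call & !pos) / sum(!pos)
  sens + spec - 1
}

#' Compare candidate DIR tests against the permutation reference
#'
#' For each candidate test, computes agreement with the reference
#' p-values: Pearson correlation of the p-values, Spearman rank
#' correlation, Pearson correlation of log p-values, and Youden's J at
#' each significance level. Genes missing in either side are dropped
#' pairwise.
#'
#' @param results named list of named numeric vectors (candidate test ->
#'   per-gene p-values).
#' @param reference named numeric vector of reference (permutation)
#'   p-values.
#' @param alphas significance levels for Youden's J.
#' @return data.frame with one row per candidate: `test`, `pearson_r_p`,
#'   `spearman_rho_rank`, `pearson_r_logp`, and one `youden_j_<alpha>`
#'   column per level.
#' @export
compare_tests <- function(results, reference,
                          alphas = c(0.05, 0.01, 0.001)) {
  stopifnot(is.list(results), !is.null(names(reference)))
  rows <- lapply(names(results), function(nm) {
    cand <- results[[nm]]
    genes <- intersect(names(cand), names(reference))
    genes <- genes[!is.na(cand[genes]) & !is.na(reference[genes])]
    if (length(genes) < 3)
      stop("fewer than 3 shared genes for candidate '", nm, "'")
    x <- cand[genes]; r <- reference[genes]
    row <- data.frame(test = nm,
                      pearson_r_p = cor(x, r),
                      spearman_rho_rank = cor(x, r, method = "spearman"),
                      pearson_r_logp = cor(log(pmax(x, 1e-300)),
                                           log(pmax(r, 1e-300))),
                      stringsAsFactors = FALSE)
    for (a in alphas)
      row[[paste0("youden_j_", a)]] <- youden_j(x, r, a)
    row
  })
  do.call(rbind, rows)
}
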