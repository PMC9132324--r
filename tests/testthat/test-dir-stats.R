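# Elementary tests, combiners, and the LDA/PCA machinery.

test_that("Welch t p-values match the closed-form evaluation", {
  expect_equal(welch_t_pvalue(c(1, 2, 3), c(2, 3, 4)), 0.2878641,
               tolerance = 1e-6)
  expect_equal(welch_t_pvalue(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(welch_t_pvalue(c(1, 2, 3), c(2, 3, 4)),
               welch_t_pvalue(c(2, 3, 4), c(1, 2, 3)))
  # degenerate: both groups constant
  expect_equal(welch_t_pvalue(c(2, 2), c(2, 2)), 1)
  expect_equal(welch_t_pvalue(c(2, 2), c(3, 3)), .Machine$double.eps)
  expect_error(welch_t_pvalue(1, c(1, 2)), ">= 2")
})

test_that("independence test matches its conditional moments and a permutation oracle", {
  # closed form: pooled (0,0,1,1), x = first two -> Z = -sqrt(3)
  expect_equal(independence_pvalue(c(0, 0), c(1, 1)), 2 * pnorm(-sqrt(3)),
               tolerance = 1e-12)
  expect_equal(independence_pvalue(c(3, 3), c(3, 3, 3)), 1)
  # location invariance
  set.seed(1)
  x <- rnorm(5); y <- rnorm(7)
  expect_equal(independence_pvalue(x, y),
               independence_pvalue(x + 10, y + 10))
  # oracle: moments of the permutation distribution of sum(x) by
  # exhaustive enumeration
  x <- c(1.2, 0.4, 2.2); y <- c(0.1, 1.7, 0.9, 2.5)
  pool <- c(x, y); n <- length(pool); nx <- length(x)
  sums <- apply(combn(n, nx), 2, function(i) sum(pool[i]))
  popvar <- mean((sums - mean(sums))^2)
  sig2 <- nx * (n - nx) / (n - 1) * sum((pool - mean(pool))^2) / n
  expect_equal(sig2, popvar, tolerance = 1e-12)
  z_oracle <- (sum(x) - mean(sums)) / sqrt(popvar)
  expect_equal(independence_pvalue(x, y), 2 * pnorm(-abs(z_oracle)),
               tolerance = 1e-10)
})

test_that("rank-sum p-values: exact small-sample enumeration and tie handling", {
  expect_equal(rank_sum_pvalue(c(1, 2), c(3, 4), "less"), 1 / 6)
  expect_equal(rank_sum_pvalue(c(1, 1), c(1, 1)), 1)
  set.seed(2)
  x <- rnorm(6); y <- rnorm(5)
  two <- rank_sum_pvalue(x, y)
  expect_lte(min(rank_sum_pvalue(x, y, "greater"),
                 rank_sum_pvalue(x, y, "less")), two)
})

test_that("Fisher's method matches the chi-square tail closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  x <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(fisher_combine(c(0.05, 0.05)), exp(-x / 2) * (1 + x / 2),
               tolerance = 1e-12)
  expect_equal(fisher_combine(0.037), 0.037, tolerance = 1e-12)
  expect_error(fisher_combine(numeric(0)), "empty")
})

test_that("harmonic-mean combination is the identity at m = 1 and adjusts the raw mean upward", {
  expect_identical(hmp_combine(0.03), 0.03)
  adj <- hmp_combine(c(0.02, 0.06))
  expect_gte(adj, 0.03)  # raw harmonic mean is 0.03, anti-conservative
  expect_lt(adj, 0.1)
  # monotone non-decreasing in each input
  base <- c(0.01, 0.05, 0.2)
  for (i in seq_along(base)) {
    lo <- base; hi <- base; hi[i] <- hi[i] * 2
    expect_lte(hmp_combine(lo), hmp_combine(hi))
  }
})

test_that("adjusted harmonic-mean p is calibrated under the null", {
  # Monte-Carlo check of the Landau-tail evaluation: for sets of
  # uniform p-values the adjusted HMP should reject at ~alpha
  set.seed(7)
  m <- 20; reps <- 1500
  rej <- mean(replicate(reps, hmp_combine(runif(m)) < 0.05))
  band <- qnorm(c(0.005, 0.995), 0.05, sqrt(0.05 * 0.95 / reps))
  expect_gt(rej, band[1])
  expect_lt(rej, band[2])
})

test_that("geometric-mean combination is the stated closed form", {
  expect_equal(geometric_combine(0.04, 0.09), 0.06)
  expect_equal(geometric_combine(0.3, 0.3), 0.3)
  expect_equal(geometric_combine(1, 1), 1)
})

test_that("BH adjustment is step-up and preserves missing values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  out <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
  # monotone in the sorted order
  set.seed(3)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("the LDA separation statistic matches the direct two-group formula", {
  # 2-isoform gene: 1-D coordinate; PT props (0, .2), Met (.4, .6)
  counts <- ratio_gene_counts(c(0, 0.2, 0.4, 0.6))
  ratios <- normalize_isoform_vectors(counts, "g1")
  grp <- setNames(rep(c("primary", "metastatic"), each = 2),
                  ratios$sample_ids)
  fit <- lda_project(ratios, grp)
  # projections are an affine image of (0,.2,.4,.6): statistic is the
  # same as for PT {0,2}, Met {4,6}: (1-5)^2/(2+2) = 4
  expect_equal(fit$summary$statistic, 4, tolerance = 1e-9)
  # identical groups
  counts2 <- ratio_gene_counts(c(0.3, 0.6, 0.3, 0.6))
  r2 <- normalize_isoform_vectors(counts2, "g1")
  expect_equal(lda_project(r2, grp)$summary$statistic, 0)
  expect_error(lda_project(ratios, grp[-1]), "group")
})

test_that("zero within-group variance yields 0 or Inf by mean equality", {
  grp <- setNames(rep(c("a", "b"), each = 2), sprintf("s%02d", 1:4))
  same <- normalize_isoform_vectors(ratio_gene_counts(rep(0.4, 4)), "g1")
  expect_equal(lda_project(same, grp)$summary$statistic, 0)
  sep <- normalize_isoform_vectors(
    ratio_gene_counts(c(0.2, 0.2, 0.8, 0.8)), "g1")
  expect_identical(lda_project(sep, grp)$summary$statistic, Inf)
})

test_that("R and C++ discriminant statistics agree on random genes", {
  for (s in 1:20) {
    n <- sample(6:14, 1)
    ratios <- random_ratios(n, sample(2:5, 1), seed = s)
    n1 <- sample(2:(n - 2), 1)
    grp <- setNames(rep(c("a", "b"), c(n1, n - n1)), ratios$sample_ids)
    r_stat <- lda_project(ratios, grp)$summary$statistic
    cpp_stat <- lda_stat_cpp(isoratio:::reduce_ratio_coords(
      ratios$proportions), as.integer(grp == "b"))
    expect_equal(r_stat, cpp_stat, tolerance = 1e-8)
  }
})

test_that("the statistic is invariant to isoform order", {
  ratios <- random_ratios(10, 4, seed = 5)
  grp <- setNames(rep(c("a", "b"), each = 5), ratios$sample_ids)
  base <- lda_project(ratios, grp)$summary$statistic
  for (i in 1:5) {
    perm <- ratios
    perm$proportions <- perm$proportions[, sample(4), drop = FALSE]
    expect_equal(lda_project(perm, grp)$summary$statistic, base,
                 tolerance = 1e-8)
  }
})

test_that("normalization drops all-zero samples and rescales rows to 1", {
  counts <- toy_counts()
  r <- normalize_isoform_vectors(counts, "gA")
  expect_equal(unname(r$proportions["s1", ]), c(5, 2) / 7)
  r3 <- normalize_isoform_vectors(counts, "gC")
  expect_identical(r3$sample_ids, "s2")
  expect_identical(r3$dropped_samples, "s1")
  expect_error(normalize_isoform_vectors(counts, "missing"),
               "not testable")
  one_iso <- isoform_counts(matrix(1:2, 1, 2,
                                   dimnames = list("i1", c("s1", "s2"))),
                            c(i1 = "g"))
  expect_error(normalize_isoform_vectors(one_iso, "g"), "single isoform")
})

test_that("PCA retains n-1 components, conserves variance, and flags degeneracy", {
  ratios <- random_ratios(12, 2, seed = 8)
  expect_identical(pca_components(ratios)$n_components, 1L)
  ratios4 <- random_ratios(12, 4, seed = 9)
  pcs <- pca_components(ratios4)
  expect_lte(pcs$n_components, 3L)
  centered <- scale(ratios4$proportions, center = TRUE, scale = FALSE)
  expect_equal(sum(pcs$variances), sum(apply(centered, 2, var)),
               tolerance = 1e-9)
  same <- normalize_isoform_vectors(ratio_gene_counts(rep(0.3, 6)), "g1")
  expect_identical(pca_components(same)$n_components, 0L)
})

test_that("exhaustive permutation p equals the labeling-enumeration fraction", {
  counts <- ratio_gene_counts(c(0.9, 0.8, 0.1, 0.2))
  ratios <- normalize_isoform_vectors(counts, "g1")
  grp <- setNames(rep(c("primary", "metastatic"), each = 2),
                  ratios$sample_ids)
  res <- lda_permutation_test(ratios, grp, n_iter = 100, seed = 1)
  expect_identical(res$method, "exhaustive")
  expect_equal(res$p, 2 / 6)
})

test_that("sampled permutation p respects the resolution floor and tracks the exact p", {
  ratios <- random_ratios(8, 2, seed = 13)
  # strong separation: group a gets the 4 smallest first-isoform shares
  o <- order(ratios$proportions[, 1])
  grp <- setNames(character(8), ratios$sample_ids)
  grp[o[1:4]] <- "a"; grp[o[5:8]] <- "b"
  ex <- lda_permutation_test(ratios, grp, method = "exhaustive")
  sa <- lda_permutation_test(ratios, grp, n_iter = 4000, seed = 2,
                             method = "sampled")
  expect_identical(sa$method, "sampled")
  expect_gte(sa$p, 1 / 4001)
  se <- sqrt(ex$p * (1 - ex$p) / 4000)
  expect_lt(abs(sa$p - ex$p), 3 * se + 1 / 4001)
})

test_that("gene-level DIR results obey the geometric-mean identity and reason codes", {
  co <- generate_cohort(cohort_config(n_primary = 15, n_metastatic = 25,
                                      n_genes = 40, seed = 17L))
  genes <- unique(co$counts$gene_of)
  res <- dir_test(co$counts, co$meta, genes = genes)
  ok <- !is.na(res$p_geo)
  expect_true(any(ok))
  expect_equal(res$p_geo[ok]^2,
               res$p_t_fisher[ok] * res$p_coin_fisher[ok],
               tolerance = 1e-12)
  single <- res$n_isoforms == 1
  expect_true(all(res$reason[single] == "single_isoform"))
  expect_true(all(is.na(res$p_geo[single])))
  # p_geo lies between its two factors
  expect_true(all(res$p_geo[ok] >=
                    pmin(res$p_t_fisher[ok], res$p_coin_fisher[ok]) - 1e-15))
  expect_true(all(res$p_geo[ok] <=
                    pmax(res$p_t_fisher[ok], res$p_coin_fisher[ok]) + 1e-15))
})

test_that("DIR results are invariant to isoform row order", {
  co <- generate_cohort(cohort_config(n_primary = 8, n_metastatic = 12,
                                      n_genes = 10,
                                      isoforms_per_gene_range = c(3, 3),
                                      seed = 23L))
  g <- unique(co$counts$gene_of)[1]
  base <- dir_test_gene(co$counts, co$meta, g)
  iso <- gene_isoforms(co$counts, g)
  reordered <- co$counts$values
  reordered[iso, ] <- reordered[rev(iso), ]
  rownames(reordered)[match(iso, rownames(reordered))] <- rev(iso)
  counts2 <- isoform_counts(reordered, co$counts$gene_of[rownames(reordered)])
  alt <- dir_test_gene(counts2, co$meta, g)
  expect_equal(alt$p_geo, base$p_geo, tolerance = 1e-9)
})

test_that("test comparison recovers perfect and inverted agreement", {
  set.seed(4)
  ref <- setNames(runif(200), paste0("g", 1:200))
  ident <- ref
  anti <- setNames(1 - ref, names(ref))
  cmp <- compare_tests(list(same = ident, anti = anti), ref)
  same_row <- cmp[cmp$test == "same", ]
  expect_equal(same_row$pearson_r_p, 1)
  expect_equal(same_row$spearman_rho_rank, 1)
  expect_equal(same_row$youden_j_0.05, 1)
  expect_equal(cmp[cmp$test == "anti", "spearman_rho_rank"], -1)
})

test_that("Youden's J is missing without both classes in the reference", {
  ref <- c(a = 0.2, b = 0.4, c = 0.9)
  expect_true(is.na(youden_j(ref, ref, alpha = 0.01)))  # no positives
  expect_true(is.na(youden_j(ref, ref, alpha = 0.99)))  # no negatives
  expect_equal(youden_j(c(0.01, 0.6, 0.7), c(0.02, 0.5, 0.8), 0.05), 1)
})
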