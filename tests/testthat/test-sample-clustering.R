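test_that("per-sample quasi-Poisson test matches the saturated-fit closed form", {
  flat <- per_sample_glm_test(c(2, 2, 2, 2), 2)
  expect_equal(flat$coefficient, 0)
  expect_equal(flat$p, 1)
  ex <- per_sample_glm_test(c(1, 3, 2, 2), 8)
  expect_equal(ex$coefficient, log(4))
  expect_equal(ex$dispersion, 1 / 3)
  expect_equal(ex$p, 0.01718603, tolerance = 1e-6)
  expect_identical(ex$sign, 1L)
  down <- per_sample_glm_test(c(50, 60, 55, 45), 0)
  expect_identical(down$sign, -1L)
  expect_gt(down$p, 0)
  expect_lt(down$p, 1)
  zero <- per_sample_glm_test(c(0, 0, 0), 0)
  expect_identical(zero$sign, 0L)
  expect_equal(zero$p, 1)
})

test_that("the closed-form fit agrees with stats::glm quasipoisson", {
  set.seed(11)
  for (i in 1:15) {
    pri <- rpois(sample(3:8, 1), lambda = runif(1, 2, 30)) +
      runif(1)  # non-integer TPM-like response
    met <- rpois(1, lambda = runif(1, 2, 40)) + 0.3
    fit <- glm(c(pri, met) ~ c(rep(0, length(pri)), 1),
               family = quasipoisson())
    s <- summary(fit)
    ours <- per_sample_glm_test(pri, met)
    # glm stops at its IRLS tolerance; agreement to ~1e-4 relative
    expect_equal(ours$coefficient, unname(coef(fit)[2]), tolerance = 1e-4)
    expect_equal(ours$dispersion, s$dispersion, tolerance = 1e-4)
    expect_equal(ours$p,
                 2 * pt(-abs(s$coefficients[2, "t value"]),
                        length(pri) - 1),
                 tolerance = 1e-4)
  }
})

test_that("matrix-wise calls equal the scalar routine", {
  co <- generate_cohort(cohort_config(n_primary = 6, n_metastatic = 4,
                                      n_genes = 15, seed = 31L))
  calls <- per_sample_calls(co$counts, co$meta)
  pri <- co$meta$sample_id[co$meta$sample_type == "primary"]
  met <- co$meta$sample_id[co$meta$sample_type == "metastatic"]
  for (iso in sample(rownames(co$counts$values), 10)) {
    for (s in met) {
      one <- per_sample_glm_test(co$counts$values[iso, pri],
                                 co$counts$values[iso, s])
      expect_equal(calls$p[iso, s], one$p, tolerance = 1e-12)
      expect_equal(unname(calls$sign[iso, s]), as.numeric(one$sign))
    }
  }
})

test_that("digitization uses direction-specific asymmetric thresholds", {
  expect_identical(digitize(0.01, 1L), 1L)
  expect_identical(digitize(0.10, -1L), -1L)
  expect_identical(digitize(0.10, 1L), 0L)
  expect_identical(digitize(0.30, -1L), 0L)
  expect_identical(digitize(0.04, 0L), 0L)
  # monotone: lowering p never turns a nonzero call to zero
  for (sgn in c(-1L, 1L)) {
    p_hi <- c(0.04, 0.15, 0.5)
    for (i in seq_along(p_hi)) {
      hi <- digitize(p_hi[i], sgn)
      lo <- digitize(p_hi[i] / 2, sgn)
      expect_gte(abs(lo), abs(hi))
    }
  }
})

test_that("recurrence filtering is strictly greater-than", {
  d <- matrix(0L, 3, 100, dimnames = list(paste0("i", 1:3), NULL))
  d[1, 1:13] <- 1L   # exactly 13% -> dropped
  d[2, 1:14] <- 1L   # > 13% -> kept
  out <- filter_recurrent(d, 0.13)
  expect_identical(rownames(out), "i2")
  all_kept <- filter_recurrent(d, 0)
  expect_identical(rownames(all_kept), c("i1", "i2"))  # all-zero row out
})

test_that("elbow k-means recovers planted blobs and degenerates to k = 1", {
  set.seed(6)
  centers <- rbind(c(0, 0), c(8, 0), c(4, 6.9))
  blobs <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(20, centers[i, 1], 0.2), rnorm(20, centers[i, 2], 0.2))))
  rownames(blobs) <- paste0("r", 1:60)
  fit <- elbow_kmeans(blobs, k_range = 1:6, seed = 2)
  expect_identical(fit$k, 3L)
  truth <- rep(1:3, each = 20)
  expect_equal(adjusted_rand_index(fit$cluster, truth), 1)
  # determinism
  fit2 <- elbow_kmeans(blobs, k_range = 1:6, seed = 2)
  expect_identical(fit$cluster, fit2$cluster)
  flat <- matrix(1, 10, 4, dimnames = list(paste0("r", 1:10), NULL))
  expect_identical(elbow_kmeans(flat, k_range = 1:5, seed = 1)$k, 1L)
  # manual override wins
  fit5 <- elbow_kmeans(blobs, k_range = 1:6, seed = 2, k_override = 5)
  expect_identical(fit5$k, 5L)
  expect_identical(length(unique(fit5$cluster)), 5L)
})

test_that("cluster enrichment matches hypergeometric enumeration", {
  assignment <- setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  labels <- setNames(rep(c("skin", "node"), 4), paste0("s", 1:8))
  labels[1:4] <- c("skin", "skin", "skin", "node")
  labels[5:8] <- c("skin", "node", "node", "node")
  res <- cluster_enrichment(assignment, labels)
  row <- res[res$cluster == "A" & res$level == "skin", ]
  expect_identical(c(row$a, row$b, row$c, row$d), c(3L, 1L, 1L, 3L))
  expect_equal(row$p, 17 / 70, tolerance = 1e-12)
  expect_equal(row$odds_ratio, 9)
  # oracle: one-sided p = sum of hypergeometric masses >= a
  oracle <- function(a, b, cc, d)
    sum(dhyper(a:(a + min(b, cc)), a + cc, b + d, a + b))
  for (r in seq_len(nrow(res)))
    expect_equal(res$p[r],
                 oracle(res$a[r], res$b[r], res$c[r], res$d[r]),
                 tolerance = 1e-10)
  # zero cell: continuity-corrected odds ratio, exact p
  assignment2 <- setNames(rep(c("A", "B"), c(3, 5)), paste0("s", 1:8))
  labels2 <- setNames(c(rep("x", 3), rep("y", 5)), paste0("s", 1:8))
  res2 <- cluster_enrichment(assignment2, labels2)
  rowx <- res2[res2$cluster == "A" & res2$level == "x", ]
  expect_equal(rowx$odds_ratio, (3.5 * 5.5) / (0.5 * 0.5))
  expect_equal(rowx$p, oracle(3, 0, 0, 5), tolerance = 1e-12)
})

test_that("infiltrate classification recovers the planted sample set", {
  cfg <- cohort_config(n_primary = 20, n_metastatic = 60, n_genes = 80,
                       frac_dir_genes = 0, frac_de_genes = 0,
                       frac_infiltrate_samples = 0.25,
                       bias_strength = 0, seed = 41L)
  co <- generate_cohort(cfg)
  immune_iso <- names(co$counts$gene_of)[co$counts$gene_of %in%
                                           co$truth$immune_genes]
  calls <- per_sample_calls(co$counts, co$meta, isoforms = immune_iso)
  dig <- digitize(calls$p, calls$sign)
  lab <- classify_infiltrate(dig, immune_iso, seed = 1)
  truth <- ifelse(colnames(dig) %in% co$truth$infiltrate_samples,
                  "infiltrate", "other")
  expect_gte(adjusted_rand_index(lab, truth), 0.8)
  # majority of planted samples individually recovered
  expect_gte(mean(lab[co$truth$infiltrate_samples] == "infiltrate"), 0.8)
  expect_identical(lab, classify_infiltrate(dig, immune_iso, seed = 1))
})

test_that("an all-zero immune program labels everything other, with a warning", {
  d <- matrix(0L, 4, 6, dimnames = list(paste0("i", 1:4),
                                        paste0("s", 1:6)))
  expect_warning(lab <- classify_infiltrate(d, c("i1", "i2")), "zero")
  expect_true(all(lab == "other"))
  expect_error(classify_infiltrate(d, "nope"), "absent")
})

test_that("the biclustering pipeline separates two planted metastatic programs", {
  sub <- generate_subgroup_cohort(n_primary = 20, n_met_a = 25,
                                  n_met_b = 25, n_isoforms = 60,
                                  program_size = 20, effect = 4,
                                  seed = 13L)
  cl <- cluster_metastatic_samples(sub$counts, sub$meta, k_range = 1:6,
                                   seed = 3)
  expect_gte(adjusted_rand_index(
    cl$sample_clusters$cluster[names(sub$truth$subgroup)],
    sub$truth$subgroup), 0.8)
})
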