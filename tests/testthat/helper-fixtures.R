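# Shared fixture builders; everything is generated in code.

toy_counts <- function() {
  vals <- matrix(c(5, 2, 0, 3, 0, 0,
                   5, 8, 10, 7, 6, 2), nrow = 6, ncol = 2,
                 dimnames = list(paste0("iso", 1:6), c("s1", "s2")))
  gene_of <- setNames(rep(c("gA", "gB", "gC"), each = 2),
                      paste0("iso", 1:6))
  isoform_counts(vals, gene_of)
}

toy_meta <- function(sample_ids, types, purity = NULL, bias = NULL,
                     batch = "batch1") {
  data.frame(sample_id = sample_ids, sample_type = types, batch = batch,
             purity = if (is.null(purity)) rep(1, length(sample_ids))
                      else purity,
             bias_score = if (is.null(bias)) rep(0, length(sample_ids))
                          else bias,
             subtype = "unknown", region = NA_character_,
             stringsAsFactors = FALSE)
}

# counts for a single two-isoform gene with explicit isoform-1
# proportions per sample, all totals equal
ratio_gene_counts <- function(prop1, sample_ids = NULL, total = 100,
                              gene = "g1") {
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_along(prop1))
  vals <- rbind(total * prop1, total * (1 - prop1))
  dimnames(vals) <- list(paste0(gene, ".", 1:2), sample_ids)
  isoform_counts(vals, setNames(rep(gene, 2), rownames(vals)))
}

# config for null cohorts: no planted effects, purity pinned at 1,
# no fragment bias, no infiltrate
null_config <- function(n_primary, n_metastatic, n_genes, seed,
                        isoforms_per_gene_range = c(2L, 4L), ...) {
  cohort_config(n_primary = n_primary, n_metastatic = n_metastatic,
                n_genes = n_genes,
                isoforms_per_gene_range = isoforms_per_gene_range,
                frac_dir_genes = 0, frac_de_genes = 0,
                frac_infiltrate_samples = 0,
                purity_beta_params = list(primary = c(1, 0),
                                          metastatic = c(1, 0)),
                bias_beta_params = list(primary = c(1, 0),
                                        metastatic = c(1, 0)),
                bias_strength = 0, seed = seed, ...)
}

adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# random ratio_matrix for a gene with n samples and k isoforms
random_ratios <- function(n, k, gene = "g1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  props <- matrix(rgamma(n * k, shape = 1), n, k)
  props <- props / rowSums(props)
  dimnames(props) <- list(sprintf("s%02d", seq_len(n)),
                          paste0(gene, ".", seq_len(k)))
  structure(list(gene_id = gene, isoform_ids = colnames(props),
                 sample_ids = rownames(props), proportions = props,
                 dropped_samples = character(0)),
            class = "ratio_matrix")
}
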