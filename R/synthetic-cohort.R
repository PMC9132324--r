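# Synthetic two-cohort generator with known ground truth. Emulates the
# statistical structure of kallisto-style isoform TPM matrices from a
# primary-vs-metastatic tumor study: per-gene isoform proportion vectors
# with group-specific switches, gene-level expression effects, tumor
# impurity mixtures (with an immune-infiltrate program), 3' fragment
# bias that skews isoform but not gene totals, batch factors, and
# junction read counts consistent with the isoform proportions.

#' Configuration for a synthetic cohort
#'
#' Validates and fills the parameter set consumed by
#' [generate_cohort]. The defaults describe a moderately sized study:
#' unbalanced groups (more metastatic than primary samples), a minority
#' of genes carrying an isoform switch, intermediate within-group
#' proportion noise, realistic purity and 3' bias score distributions,
#' and a handful of processing batches.
#'
#' @param n_primary,n_metastatic group sizes.
#' @param n_genes number of genes.
#' @param isoforms_per_gene_range integer pair, min >= 1; isoform counts
#'   are drawn uniformly from this range.
#' @param frac_dir_genes fraction of genes given an isoform-ratio switch
#'   in the metastatic group.
#' @param dir_delta proportion mass (in (0,1)) moved between the two
#'   switched isoforms in metastatic samples.
#' @param frac_de_genes fraction of genes given a gene-level expression
#'   effect in the metastatic group.
#' @param de_log2fc_range positive pair; absolute log2 fold changes are
#'   uniform on this range, sign random.
#' @param dirichlet_concentration within-group concentration of the
#'   per-sample Dirichlet proportion noise (larger = less noise).
#' @param frac_infiltrate_samples fraction of metastatic samples given
#'   the immune-infiltrate contamination program.
#' @param purity_beta_params list with elements `primary` and
#'   `metastatic`, each a Beta(a, b) shape pair for the per-sample tumor
#'   purity; a second shape of 0 is the sentinel for purity exactly 1.
#' @param bias_beta_params same structure for the per-sample 3' bias
#'   score; second shape 0 pins the score at 0 (no bias).
#' @param bias_strength global strength (0-1) of the 3' fragment bias
#'   transfer; 0 disables it.
#' @param n_batches number of processing batches.
#' @param batch_sd standard deviation (log scale) of per-batch per-gene
#'   multiplicative factors.
#' @param junction_depth expected junction reads per event and sample.
#' @param seed integer seed; identical config and seed give bit-identical
#'   cohorts.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_primary = 50L, n_metastatic = 150L,
                          n_genes = 200L,
                          isoforms_per_gene_range = c(1L, 6L),
                          frac_dir_genes = 0.1, dir_delta = 0.3,
                          frac_de_genes = 0.2,
                          de_log2fc_range = c(0.5, 2),
                          dirichlet_concentration = 20,
                          frac_infiltrate_samples = 0.2,
                          purity_beta_params = list(primary = c(12, 3),
                                                    metastatic = c(8, 3)),
                          bias_beta_params = list(primary = c(10, 9),
                                                  metastatic = c(10, 9)),
                          bias_strength = 0.5,
                          n_batches = 4L, batch_sd = 0.2,
                          junction_depth = 100, seed = 1L) {
  cfg <- list(n_primary = as.integer(n_primary),
              n_metastatic = as.integer(n_metastatic),
              n_genes = as.integer(n_genes),
              isoforms_per_gene_range = as.integer(isoforms_per_gene_range),
              frac_dir_genes = frac_dir_genes, dir_delta = dir_delta,
              frac_de_genes = frac_de_genes,
              de_log2fc_range = de_log2fc_range,
              dirichlet_concentration = dirichlet_concentration,
              frac_infiltrate_samples = frac_infiltrate_samples,
              purity_beta_params = purity_beta_params,
              bias_beta_params = bias_beta_params,
              bias_strength = bias_strength,
              n_batches = as.integer(n_batches), batch_sd = batch_sd,
              junction_depth = junction_depth, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_primary >= 1, n_metastatic >= 1, n_genes >= 1,
              length(isoforms_per_gene_range) == 2,
              isoforms_per_gene_range[1] >= 1,
              isoforms_per_gene_range[1] <= isoforms_per_gene_range[2],
              frac_dir_genes >= 0, frac_dir_genes <= 1,
              dir_delta > 0, dir_delta < 1,
              frac_de_genes >= 0, frac_de_genes <= 1,
              all(de_log2fc_range > 0), length(de_log2fc_range) == 2,
              dirichlet_concentration > 0,
              frac_infiltrate_samples >= 0, frac_infiltrate_samples <= 1,
              bias_strength >= 0, bias_strength <= 1,
              n_batches >= 1, batch_sd >= 0, junction_depth > 0)
  })
  for (side in c("primary", "metastatic")) {
    stopifnot(length(cfg$purity_beta_params[[side]]) == 2,
              all(cfg$purity_beta_params[[side]] >= 0),
              length(cfg$bias_beta_params[[side]]) == 2,
              all(cfg$bias_beta_params[[side]] >= 0))
  }
  structure(cfg, class = "cohort_config")
}

# Beta draw with shape2 == 0 meaning a point mass at the upper bound
# `at1` (1 for purity, 0 for bias via `at1 = 0` and reflection).
rbeta_or_point <- function(n, shapes, point) {
  if (shapes[2] == 0) rep(point, n) else rbeta(n, shapes[1], shapes[2])
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-3))
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Mix a tumor expression profile with a contaminant
#'
#' Linear impurity mixture: `purity * tumor + (1 - purity) *
#' contaminant`, elementwise over the isoform index. Models bulk samples
#' containing non-tumor (immune/stromal) cells.
#'
#' @param tumor_profile,contaminant_profile non-negative abundance
#'   vectors over the same isoform index (names compared when present).
#' @param purity tumor fraction in \[0, 1\].
#' @return mixed abundance vector.
#' @export
apply_impurity <- function(tumor_profile, contaminant_profile, purity) {
  if (length(tumor_profile) != length(contaminant_profile))
    stop("profiles have different isoform index sets")
  if (!is.null(names(tumor_profile)) &&
      !is.null(names(contaminant_profile)) &&
      !identical(names(tumor_profile), names(contaminant_profile)))
    stop("profiles have different isoform index sets")
  if (purity < 0 || purity > 1) stop("purity must be in [0, 1]")
  purity * tumor_profile + (1 - purity) * contaminant_profile
}

#' Skew one gene's isoform abundances by 3' fragment bias
#'
#' RNA degradation under poly(A)-primed protocols inflates the apparent
#' abundance of a gene's 3'-end fragment isoform at the expense of the
#' full-length isoforms, while leaving the gene total untouched. A
#' fraction `f = bias_strength * max(0, (bias_score - 0.4) / 0.6)` of
#' the total mass of the non-fragment isoforms is transferred onto the
#' fragment isoform; the sum over isoforms is preserved exactly. Genes
#' with no designated fragment isoform are returned unchanged.
#'
#' @param gene_counts named abundance vector for one gene's isoforms.
#' @param fragment_isoform id of the 3' fragment isoform, or `NA`/`NULL`
#'   when the gene has none.
#' @param bias_score per-sample 3' bias score in \[0, 1\].
#' @param bias_strength global transfer strength in \[0, 1\].
#' @return abundance vector with the same names and the same sum.
#' @export
apply_fragment_bias <- function(gene_counts, fragment_isoform,
                                bias_score, bias_strength) {
  if (is.null(fragment_isoform) || is.na(fragment_isoform))
    return(gene_counts)
  if (!fragment_isoform %in% names(gene_counts))
    return(gene_counts)
  f <- bias_strength * max(0, (bias_score - 0.4) / 0.6)
  if (f <= 0) return(gene_counts)
  others <- setdiff(names(gene_counts), fragment_isoform)
  moved <- f * sum(gene_counts[others])
  out <- gene_counts
  out[others] <- out[others] * (1 - f)
  out[fragment_isoform] <- out[fragment_isoform] + moved
  out
}

#' Generate a synthetic two-cohort isoform study
#'
#' Draws a full cohort under the configuration: per-gene baseline
#' isoform proportions (symmetric Dirichlet), group-specific switches
#' for the designated DIR genes (mass `dir_delta` moved between two
#' isoforms in the metastatic group), per-sample proportions redrawn
#' from a Dirichlet centered on the group proportions, log-normal gene
#' totals with expression effects and batch factors, impurity mixing
#' against an immune (infiltrate samples) or stromal (others)
#' contaminant profile, and finally the 3' fragment bias transform.
#' Ground truth records every planted effect.
#'
#' @param config a [cohort_config].
#' @return list of class `synthetic_cohort` with elements `counts` (an
#'   [isoform_counts]), `meta` (metadata data.frame), `truth` (planted
#'   effects: `dir_genes`, `de_genes`, `immune_genes`,
#'   `infiltrate_samples`, `fragment_isoforms`, `event_map`) and
#'   `rna_proportions` (named list gene -> samples x isoforms matrix of
#'   the impurity-mixed, bias-free isoform proportions that junction
#'   reads are drawn from).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 8L)

  ## --- gene/isoform structure -------------------------------------
  set.seed(stage_seed[1L])
  n_genes <- config$n_genes
  rng <- config$isoforms_per_gene_range
  n_iso <- if (rng[1] == rng[2]) rep(rng[1], n_genes) else
    sample(rng[1]:rng[2], n_genes, replace = TRUE)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  iso_ids <- unlist(lapply(seq_len(n_genes), function(i)
    paste0(gene_ids[i], ".", seq_len(n_iso[i]))))
  gene_of <- setNames(rep(gene_ids, n_iso), iso_ids)

  multi <- gene_ids[n_iso >= 2]
  n_immune <- round(0.10 * n_genes)
  immune_genes <- sort(sample(gene_ids, n_immune))
  eligible_dir <- setdiff(multi, immune_genes)
  n_dir <- round(config$frac_dir_genes * n_genes)
  if (n_dir > 0 && length(eligible_dir) == 0)
    stop("no multi-isoform genes eligible for isoform switches")
  if (n_dir > length(eligible_dir))
    stop("frac_dir_genes too large for the available multi-isoform genes")
  dir_gene_ids <- sort(sample(eligible_dir, n_dir))
  eligible_de <- setdiff(gene_ids, immune_genes)
  n_de <- round(config$frac_de_genes * n_genes)
  if (n_de > length(eligible_de))
    stop("frac_de_genes too large")
  de_gene_ids <- sort(sample(eligible_de, n_de))

  ## --- baseline and group proportions -----------------------------
  set.seed(stage_seed[2L])
  base_props <- lapply(seq_len(n_genes), function(i)
    setNames(rdirichlet1(rep(1, n_iso[i])),
             paste0(gene_ids[i], ".", seq_len(n_iso[i]))))
  names(base_props) <- gene_ids
  met_props <- base_props
  dir_truth <- list()
  for (g in dir_gene_ids) {
    p <- base_props[[g]]
    src <- which.max(p)
    # guarantee the source isoform carries enough mass to give up delta
    need <- config$dir_delta + 0.05
    if (p[src] < need) {
      rest <- sum(p[-src])
      p[-src] <- if (rest > 0) p[-src] * (1 - need) / rest else
        rep((1 - need) / (length(p) - 1), length(p) - 1)
      p[src] <- need
      base_props[[g]] <- p
    }
    tgt <- if (length(p) == 2) setdiff(seq_along(p), src) else
      order(p, decreasing = TRUE)[2L]
    q <- p
    q[src] <- q[src] - config$dir_delta
    q[tgt] <- q[tgt] + config$dir_delta
    met_props[[g]] <- q
    dir_truth[[g]] <- list(isoforms = names(p)[c(src, tgt)],
                           delta = config$dir_delta)
  }

  ## --- samples, batches, QC scores --------------------------------
  set.seed(stage_seed[3L])
  n_p <- config$n_primary; n_m <- config$n_metastatic
  sample_ids <- c(sprintf("P%03d", seq_len(n_p)),
                  sprintf("M%03d", seq_len(n_m)))
  sample_type <- rep(c("primary", "metastatic"), c(n_p, n_m))
  batch <- paste0("batch", sample(config$n_batches, n_p + n_m,
                                  replace = TRUE))
  purity <- numeric(n_p + n_m)
  bias_score <- numeric(n_p + n_m)
  for (side in c("primary", "metastatic")) {
    idx <- sample_type == side
    purity[idx] <- rbeta_or_point(sum(idx),
                                  config$purity_beta_params[[side]], 1)
    bias_score[idx] <- rbeta_or_point(sum(idx),
                                      config$bias_beta_params[[side]], 0)
  }
  n_inf <- round(config$frac_infiltrate_samples * n_m)
  infiltrate_samples <- sort(sample(sample_ids[sample_type == "metastatic"],
                                    n_inf))
  subtype <- sample(c("BRAF", "RAS", "NF1", "tripleWT", "unknown"),
                    n_p + n_m, replace = TRUE,
                    prob = c(0.35, 0.22, 0.07, 0.11, 0.25))
  region <- ifelse(sample_type == "primary", "skin",
                   sample(c("skin_soft_tissue", "lymph_node", "distant"),
                          n_p + n_m, replace = TRUE))
  meta <- data.frame(sample_id = sample_ids, sample_type = sample_type,
                     batch = batch, purity = purity,
                     bias_score = bias_score, subtype = subtype,
                     region = region, stringsAsFactors = FALSE)

  ## --- expression: totals, proportions, counts --------------------
  set.seed(stage_seed[4L])
  base_total <- rlnorm(n_genes, meanlog = log(50), sdlog = 1)
  names(base_total) <- gene_ids
  lfc <- setNames(runif(n_de, config$de_log2fc_range[1],
                        config$de_log2fc_range[2]) *
                    sample(c(-1, 1), n_de, replace = TRUE),
                  de_gene_ids)
  batch_lf <- matrix(rnorm(n_genes * config$n_batches, 0, config$batch_sd),
                     n_genes, config$n_batches,
                     dimnames = list(gene_ids,
                                     paste0("batch",
                                            seq_len(config$n_batches))))
  is_met <- sample_type == "metastatic"
  # per-sample gene totals (log scale): base + batch + noise + effect
  log_tot <- matrix(log(base_total), n_genes, n_p + n_m) +
    batch_lf[, batch] +
    matrix(rnorm(n_genes * (n_p + n_m), 0, 0.3), n_genes)
  if (n_de > 0)
    log_tot[de_gene_ids, is_met] <- log_tot[de_gene_ids, is_met] +
      lfc[de_gene_ids] * log(2)
  totals <- exp(log_tot)
  dimnames(totals) <- list(gene_ids, sample_ids)

  set.seed(stage_seed[5L])
  values <- matrix(0, length(iso_ids), n_p + n_m,
                   dimnames = list(iso_ids, sample_ids))
  conc <- config$dirichlet_concentration
  for (i in seq_len(n_genes)) {
    g <- gene_ids[i]
    iso <- names(base_props[[g]])
    for (s in seq_len(n_p + n_m)) {
      centre <- if (is_met[s]) met_props[[g]] else base_props[[g]]
      pr <- if (n_iso[i] == 1) 1 else rdirichlet1(conc * centre)
      values[iso, s] <- totals[g, s] * pr
    }
  }

  ## --- impurity ----------------------------------------------------
  set.seed(stage_seed[6L])
  immune_boost <- 20
  contam_total <- base_total
  contam_total[immune_genes] <- contam_total[immune_genes] * immune_boost
  immune_profile <- unlist(lapply(gene_ids, function(g)
    contam_total[g] * base_props[[g]]))
  stromal_profile <- unlist(lapply(gene_ids, function(g)
    base_total[g] * base_props[[g]]))
  names(immune_profile) <- names(stromal_profile) <- iso_ids
  for (s in seq_len(n_p + n_m)) {
    if (purity[s] >= 1) next
    contam <- if (sample_ids[s] %in% infiltrate_samples) immune_profile
              else stromal_profile
    values[, s] <- apply_impurity(values[, s], contam, purity[s])
  }
  # junction reads reflect the mixed RNA pool but are untouched by the
  # 3' quantification bias, so capture proportions here
  rna_proportions <- lapply(gene_ids[n_iso >= 2], function(g) {
    iso <- names(base_props[[g]])
    sub <- t(values[iso, , drop = FALSE])
    tot <- rowSums(sub)
    sub[tot > 0, ] <- sub[tot > 0, , drop = FALSE] / tot[tot > 0]
    sub
  })
  names(rna_proportions) <- gene_ids[n_iso >= 2]

  ## --- 3' fragment bias -------------------------------------------
  set.seed(stage_seed[7L])
  frag_genes <- multi[runif(length(multi)) < 0.5]
  fragment_isoforms <- setNames(vapply(frag_genes, function(g) {
    iso <- names(base_props[[g]])
    iso[length(iso)]
  }, character(1)), frag_genes)
  if (config$bias_strength > 0) {
    for (g in frag_genes) {
      iso <- names(base_props[[g]])
      for (s in seq_len(n_p + n_m)) {
        values[iso, s] <- apply_fragment_bias(values[iso, s],
                                              fragment_isoforms[[g]],
                                              bias_score[s],
                                              config$bias_strength)
      }
    }
  }

  ## --- junction events --------------------------------------------
  set.seed(stage_seed[8L])
  event_map <- list()
  ev_genes <- dir_gene_ids
  null_pool <- setdiff(multi, c(dir_gene_ids, immune_genes))
  if (length(null_pool))
    ev_genes <- c(ev_genes,
                  sort(sample(null_pool,
                              min(length(null_pool), max(length(dir_gene_ids),
                                                         5L)))))
  for (k in seq_along(ev_genes)) {
    g <- ev_genes[k]
    inc <- if (g %in% dir_gene_ids) dir_truth[[g]]$isoforms[1L] else
      names(base_props[[g]])[1L]
    type <- if (g %in% dir_gene_ids || k %% 2 == 0) "skipped_exon" else
      "alt_promoter"
    event_map[[g]] <- junction_event(g, type,
                                     inclusion_isoforms = inc,
                                     favored_direction = "greater",
                                     anchor = 10000L * k)
  }

  structure(list(counts = isoform_counts(values, gene_of),
                 meta = meta,
                 truth = list(dir_genes = dir_truth,
                              de_genes = lfc,
                              immune_genes = immune_genes,
                              infiltrate_samples = infiltrate_samples,
                              fragment_isoforms = fragment_isoforms,
                              event_map = event_map),
                 rna_proportions = rna_proportions,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: ", nrow(x$counts$values), " isoforms x ",
      ncol(x$counts$values), " samples (",
      sum(x$meta$sample_type == "primary"), " primary / ",
      sum(x$meta$sample_type == "metastatic"), " metastatic); ",
      length(x$truth$dir_genes), " DIR genes, ",
      length(x$truth$de_genes), " DE genes\n", sep = "")
  invisible(x)
}

#' Generate junction read counts consistent with isoform proportions
#'
#' For each event, draws per-sample split-read counts from independent
#' Poisson distributions tied to the sample's inclusion proportion
#' \eqn{\psi} (the summed proportion of isoforms containing the
#' alternative exon, or driven by the alternative promoter). For a
#' skipped-exon event the two inclusion-flank junctions have mean
#' `depth * psi` each and the skipping junction mean `depth * (1 -
#' psi)`; two-way events use the analogous two-junction scheme.
#'
#' @param ratio_matrix named list, gene id -> samples x isoforms matrix
#'   of isoform proportions (e.g. `rna_proportions` from
#'   [generate_cohort]).
#' @param events named list of [junction_event]s (gene id -> event).
#' @param depth expected reads per junction triple (positive).
#' @param seed integer seed.
#' @return junction count table: data.frame with columns `chrom`,
#'   `intron_start`, `intron_end`, `strand`, `sample_id`,
#'   `unique_read_count`.
#' @export
generate_junction_counts <- function(ratio_matrix, events, depth, seed) {
  if (depth <= 0) stop("depth must be positive")
  missing <- setdiff(names(events), names(ratio_matrix))
  if (length(missing))
    stop("events for genes absent from ratio_matrix: ",
         paste(head(missing, 3), collapse = ", "))
  set.seed(seed)
  rows <- list()
  for (g in names(events)) {
    ev <- events[[g]]
    props <- ratio_matrix[[g]]
    inc <- intersect(ev$inclusion_isoforms, colnames(props))
    psi <- rowSums(props[, inc, drop = FALSE])
    jn <- ev$junctions
    counts <- switch(ev$event_type,
      skipped_exon = cbind(flank_left = rpois(length(psi), depth * psi),
                           flank_right = rpois(length(psi), depth * psi),
                           skip = rpois(length(psi), depth * (1 - psi))),
      cbind(junction_a = rpois(length(psi), depth * psi),
            junction_b = rpois(length(psi), depth * (1 - psi))))
    for (role in colnames(counts)) {
      j <- jn[jn$role == role, ]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = j$chrom, intron_start = j$intron_start,
        intron_end = j$intron_end, strand = j$strand,
        sample_id = rownames(props),
        unique_read_count = counts[, role],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic cohort with two planted metastatic subgroups
#'
#' Builds a per-isoform count matrix in which two disjoint subsets of
#' metastatic samples each up-regulate a disjoint program of isoforms
#' relative to the primary pool — the structure targeted by the
#' per-sample outlier-calling and biclustering pipeline. Each isoform is
#' treated as its own gene (the clustering stage works isoform-wise).
#'
#' @param n_primary,n_met_a,n_met_b group sizes.
#' @param n_isoforms total isoforms; the first `program_size` form
#'   program A, the next `program_size` program B.
#' @param program_size isoforms per subgroup program.
#' @param effect multiplicative up-regulation of a program in its
#'   subgroup.
#' @param seed integer seed.
#' @return list with `counts` (an [isoform_counts]), `meta`, and `truth`
#'   (`subgroup`: named vector over metastatic samples, `programs`:
#'   list of isoform id vectors).
#' @export
generate_subgroup_cohort <- function(n_primary = 40L, n_met_a = 60L,
                                     n_met_b = 60L, n_isoforms = 120L,
                                     program_size = 30L, effect = 4,
                                     seed = 1L) {
  stopifnot(2 * program_size <= n_isoforms)
  set.seed(seed)
  iso_ids <- sprintf("iso%04d", seq_len(n_isoforms))
  prog_a <- iso_ids[seq_len(program_size)]
  prog_b <- iso_ids[program_size + seq_len(program_size)]
  sample_ids <- c(sprintf("P%03d", seq_len(n_primary)),
                  sprintf("MA%03d", seq_len(n_met_a)),
                  sprintf("MB%03d", seq_len(n_met_b)))
  grp <- rep(c("primary", "met_a", "met_b"),
             c(n_primary, n_met_a, n_met_b))
  base <- rlnorm(n_isoforms, meanlog = log(20), sdlog = 0.8)
  vals <- matrix(rlnorm(n_isoforms * length(sample_ids), 0, 0.4),
                 n_isoforms, length(sample_ids)) * base
  dimnames(vals) <- list(iso_ids, sample_ids)
  vals[prog_a, grp == "met_a"] <- vals[prog_a, grp == "met_a"] * effect
  vals[prog_b, grp == "met_b"] <- vals[prog_b, grp == "met_b"] * effect
  meta <- data.frame(sample_id = sample_ids,
                     sample_type = ifelse(grp == "primary", "primary",
                                          "metastatic"),
                     batch = "batch1", purity = 1, bias_score = 0,
                     subtype = "unknown", region = NA_character_,
                     stringsAsFactors = FALSE)
  truth_sub <- setNames(grp[grp != "primary"], sample_ids[grp != "primary"])
  list(counts = isoform_counts(vals, setNames(iso_ids, iso_ids)),
       meta = meta,
       truth = list(subgroup = truth_sub,
                    programs = list(A = prog_a, B = prog_b)))
}
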