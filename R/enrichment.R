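# Percentile-threshold enrichment of ranked gene lists for kinase
# phylogenetic groups and biological-process sets, with an empirical
# false-discovery-rate companion.

#' Top fraction of a ranked gene list
#'
#' Takes the top `ceiling(fraction * length)` genes of a list ranked by
#' ascending p-value. Only genes that actually received a p-value should
#' be in the list; ties at the boundary are broken by stable input
#' order. Ceiling rounding gives e.g. 27 of 538 and 24 of 468 genes at
#' the 5% threshold.
#'
#' @param ranked_genes character vector of gene ids ordered by ascending
#'   p-value.
#' @param fraction percentile threshold in (0, 1).
#' @return character vector, the foreground gene set.
#' @export
percentile_foreground <- function(ranked_genes, fraction) {
  if (!length(ranked_genes)) stop("ranked gene list is empty")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ranked_genes[seq_len(ceiling(fraction * length(ranked_genes)))]
}

#' Annotation-set enrichment of a foreground against its universe
#'
#' One-sided hypergeometric (Fisher exact) enrichment test per
#' annotation set, with the background taken as the universe minus the
#' foreground (the "remaining" genes). P-values are deliberately not
#' multiplicity-adjusted — annotation sets are strongly dependent and
#' share the constrained universe, so standard FDR corrections
#' misrepresent the error rate; see [empirical_fdr] for the replicated
#' alternative control. The odds ratio comes from the raw 2x2 cells,
#' with 0.5 added to every cell only when some cell is zero.
#'
#' @param foreground gene set, must be a subset of `universe`.
#' @param universe all tested genes.
#' @param annotation_sets named list of gene sets; each is intersected
#'   with the universe before testing.
#' @return data.frame with columns `annotation_id`, `a`, `b`, `c`, `d`
#'   (significant-and-annotated, significant-not, background-annotated,
#'   background-not), `odds_ratio`, `p`.
#' @export
set_enrichment <- function(foreground, universe, annotation_sets) {
  if (length(setdiff(foreground, universe)))
    stop("foreground contains genes outside the universe")
  n_univ <- length(universe)
  n_fg <- length(foreground)
  rows <- lapply(names(annotation_sets), function(id) {
    ann <- intersect(annotation_sets[[id]], universe)
    a <- length(intersect(foreground, ann))
    b <- n_fg - a
    cc <- length(ann) - a
    d <- n_univ - n_fg - cc
    # P(overlap >= a) under sampling n_fg genes from the universe
    p <- phyper(a - 1, length(ann), n_univ - length(ann), n_fg,
                lower.tail = FALSE)
    cells <- c(a, b, cc, d)
    if (any(cells == 0)) cells <- cells + 0.5
    data.frame(annotation_id = id, a = a, b = b, c = cc, d = d,
               odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
               p = min(p, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kinase phylogenetic group enrichment at percentile thresholds
#'
#' Applies [set_enrichment] at each percentile threshold with the kinase
#' phylogenetic groups as annotation sets and the full ranked list as
#' the universe. P-values are unadjusted, as for the biological-process
#' sets.
#'
#' @param ranked_genes gene ids ordered by ascending p-value; every gene
#'   must carry a kinase group.
#' @param kinase_group named character vector, gene id -> group (e.g.
#'   from [read_kinome_annotation]).
#' @param fractions percentile thresholds.
#' @return data.frame: one row per (group, fraction), [set_enrichment]
#'   columns plus `threshold_fraction`.
#' @export
kinase_group_enrichment <- function(ranked_genes, kinase_group,
                                    fractions = c(0.05, 0.10, 0.20,
                                                  0.40)) {
  missing <- setdiff(ranked_genes, names(kinase_group))
  if (length(missing))
    stop("genes without a kinase group: ",
         paste(head(missing, 3), collapse = ", "))
  groups <- split(names(kinase_group), kinase_group)
  rows <- lapply(fractions, function(f) {
    fg <- percentile_foreground(ranked_genes, f)
    res <- set_enrichment(fg, ranked_genes, groups)
    res$threshold_fraction <- f
    res
  })
  do.call(rbind, rows)
}

#' Empirical false discovery rate for set enrichment
#'
#' Draws random foregrounds of the observed size from the universe and
#' counts how many annotation sets pass `alpha` per draw. The mean
#' random count estimates the expected number of spurious enrichments;
#' dividing by the observed count gives an empirical FDR.
#'
#' @param annotation_sets named list of gene sets.
#' @param universe all tested genes.
#' @param foreground_size size of the random foregrounds.
#' @param n_random number of random draws.
#' @param alpha significance threshold on the unadjusted enrichment p.
#' @param seed integer seed.
#' @param observed_count optional observed number of sets with
#'   p < `alpha`; when given, the ratio mean-random/observed is
#'   reported.
#' @return list with `mean_random_count`, `random_counts` and
#'   `fdr_ratio` (`NA` without `observed_count`).
#' @export
empirical_fdr <- function(annotation_sets, universe, foreground_size,
                          n_random, alpha = 0.05, seed = 1L,
                          observed_count = NULL) {
  stopifnot(foreground_size <= length(universe), n_random >= 1)
  set.seed(seed)
  counts <- vapply(seq_len(n_random), function(i) {
    fg <- sample(universe, foreground_size)
    sum(set_enrichment(fg, universe, annotation_sets)$p < alpha)
  }, numeric(1))
  mean_count <- mean(counts)
  list(mean_random_count = mean_count, random_counts = counts,
       fdr_ratio = if (is.null(observed_count)) NA_real_ else
         mean_count / observed_count)
}
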