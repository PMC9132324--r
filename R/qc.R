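#' Quality-control filtering of samples
#'
#' Applies the two sample-level filters used throughout the pipeline:
#' samples with consensus purity strictly below `purity_min` are removed,
#' as are samples with a 3' bias score strictly above `bias_max`. The
#' boundaries are retained (purity exactly 0.70 passes, bias exactly 0.55
#' passes). A sample missing the score for an active filter is excluded
#' with reason `"missing"`. Either filter can be disabled by passing
#' `NA`.
#'
#' @param meta metadata data.frame (see [read_sample_metadata]).
#' @param purity_min minimum retained purity (default 0.70), or `NA` to
#'   disable the purity filter.
#' @param bias_max maximum retained 3' bias score (default 0.55), or
#'   `NA` to disable the bias filter.
#' @return a list with `retained` (character vector of sample ids, input
#'   order) and `excluded` (data.frame with columns `sample_id`,
#'   `reason`; reasons are `"purity"`, `"bias"` or `"missing"`).
#' @examples
#' meta <- data.frame(sample_id = c("a", "b", "c"),
#'                    sample_type = "primary", batch = "B1",
#'                    purity = c(0.70, 0.69, 0.9),
#'                    bias_score = c(0.55, 0.5, 0.56),
#'                    subtype = "unknown", region = NA)
#' filter_samples(meta)  # retains only "a"
#' @export
filter_samples <- function(meta, purity_min = 0.70, bias_max = 0.55) {
  n <- nrow(meta)
  reason <- rep(NA_character_, n)
  use_purity <- !is.na(purity_min)
  use_bias <- !is.na(bias_max)
  if (use_purity) {
    miss <- is.na(meta$purity)
    reason[miss & is.na(reason)] <- "missing"
    reason[!miss & meta$purity < purity_min & is.na(reason)] <- "purity"
  }
  if (use_bias) {
    miss <- is.na(meta$bias_score)
    reason[miss & is.na(reason)] <- "missing"
    reason[!miss & meta$bias_score > bias_max & is.na(reason)] <- "bias"
  }
  keep <- is.na(reason)
  list(retained = meta$sample_id[keep],
       excluded = data.frame(sample_id = meta$sample_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' One-by-one sample-removal sensitivity of a DIR p-value
#'
#' Post-hoc diagnostic for a single gene: samples are removed one at a
#' time in order of a QC score (highest 3' bias first, lowest purity
#' first, or their reverses) and the gene's DIR p-value recomputed after
#' each removal. A DIR signal that is driven by low-quality samples loses
#' significance quickly when those samples are removed first, but slowly
#' under the reverse ordering.
#'
#' @param counts an [isoform_counts] object.
#' @param meta metadata data.frame covering the samples of `counts`.
#' @param gene gene id to test.
#' @param order_key one of `"bias_desc"`, `"bias_asc"`, `"purity_asc"`,
#'   `"purity_desc"`; determines the removal order. Samples missing the
#'   score are never removed.
#' @param test function `(counts, meta, gene) -> p-value` used at each
#'   step; e.g. a wrapper around [dir_test_gene].
#' @param max_removed maximum number of samples to remove.
#' @param sample_type optionally restrict removal to `"primary"` or
#'   `"metastatic"` samples only.
#' @return data.frame with columns `n_removed`, `removed_sample` (NA for
#'   the first row) and `p`. When a removal would leave a group with
#'   fewer than 2 usable samples the sequence is truncated and the
#'   attribute `truncated` is set to `TRUE`.
#' @export
sample_removal_sensitivity <- function(counts, meta, gene,
                                       order_key = c("bias_desc", "bias_asc",
                                                     "purity_asc",
                                                     "purity_desc"),
                                       test, max_removed = 10L,
                                       sample_type = NULL) {
  order_key <- match.arg(order_key)
  meta <- meta[meta$sample_id %in% colnames(counts$values), , drop = FALSE]
  pool <- meta
  if (!is.null(sample_type))
    pool <- pool[pool$sample_type == sample_type, , drop = FALSE]
  score <- switch(order_key,
                  bias_desc = , bias_asc = pool$bias_score,
                  purity_asc = , purity_desc = pool$purity)
  pool <- pool[!is.na(score), , drop = FALSE]
  score <- score[!is.na(score)]
  decreasing <- order_key %in% c("bias_desc", "purity_desc")
  removal_order <- pool$sample_id[order(score, decreasing = decreasing)]
  removal_order <- head(removal_order, max_removed)

  kept <- meta$sample_id
  out <- data.frame(n_removed = integer(0), removed_sample = character(0),
                    p = numeric(0), stringsAsFactors = FALSE)
  truncated <- FALSE
  for (k in 0:length(removal_order)) {
    if (k > 0) kept <- setdiff(kept, removal_order[k])
    sub_meta <- meta[meta$sample_id %in% kept, , drop = FALSE]
    # a group must keep >= 2 samples with nonzero counts for the gene
    iso <- gene_isoforms(counts, gene)
    totals <- colSums(counts$values[iso, kept, drop = FALSE])
    usable <- kept[totals > 0]
    types <- sub_meta$sample_type[match(usable, sub_meta$sample_id)]
    if (sum(types == "primary") < 2 || sum(types == "metastatic") < 2) {
      truncated <- TRUE
      break
    }
    p <- test(subset_samples(counts, kept), sub_meta, gene)
    out <- rbind(out, data.frame(
      n_removed = k,
      removed_sample = if (k > 0) removal_order[k] else NA_character_,
      p = p, stringsAsFactors = FALSE))
  }
  attr(out, "truncated") <- truncated
  out
}
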