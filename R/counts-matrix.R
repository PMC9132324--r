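#' Isoform abundance matrix with gene mapping
#'
#' Container for isoform-level abundances (TPM scale) across samples,
#' together with the isoform-to-gene map. Rows are isoforms, columns are
#' samples. Values must be non-negative and finite; every isoform belongs
#' to exactly one gene.
#'
#' @param values numeric matrix, isoforms x samples, with rownames
#'   (isoform ids) and colnames (sample ids).
#' @param gene_of named character vector mapping isoform id to gene id;
#'   names must cover the rownames of `values`.
#' @return an object of class `isoform_counts`: a list with elements
#'   `values` and `gene_of`.
#' @examples
#' m <- matrix(c(5, 5, 2, 8), 2, 2,
#'             dimnames = list(c("iso1", "iso2"), c("s1", "s2")))
#' isoform_counts(m, c(iso1 = "geneA", iso2 = "geneA"))
#' @export
isoform_counts <- function(values, gene_of) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have isoform rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate isoform id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values)) || any(values < 0)) {
    bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)[1L, ]
    stop("negative or non-finite abundance at isoform '",
         rownames(values)[bad[1L]], "', sample '",
         colnames(values)[bad[2L]], "'")
  }
  gene_of <- gene_of[rownames(values)]
  if (any(is.na(gene_of)))
    stop("isoforms without a gene mapping: ",
         paste(rownames(values)[is.na(gene_of)][1:min(3, sum(is.na(gene_of)))],
               collapse = ", "))
  structure(list(values = values, gene_of = gene_of),
            class = "isoform_counts")
}

#' @export
print.isoform_counts <- function(x, ...) {
  cat("isoform_counts: ", nrow(x$values), " isoforms / ",
      length(unique(x$gene_of)), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.isoform_counts <- function(x) dim(x$values)

#' Isoform ids belonging to one gene
#'
#' @param counts an [isoform_counts] object.
#' @param gene gene id.
#' @return character vector of isoform ids, in matrix row order.
#' @export
gene_isoforms <- function(counts, gene) {
  names(counts$gene_of)[counts$gene_of == gene]
}

#' Subset an isoform matrix by sample ids
#'
#' @param counts an [isoform_counts] object.
#' @param sample_ids sample ids to keep, in the requested order.
#' @return an [isoform_counts] restricted to those samples.
#' @export
subset_samples <- function(counts, sample_ids) {
  missing <- setdiff(sample_ids, colnames(counts$values))
  if (length(missing))
    stop("unknown sample ids: ", paste(head(missing, 3), collapse = ", "))
  isoform_counts(counts$values[, sample_ids, drop = FALSE], counts$gene_of)
}
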