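# Readers and writers for the pipeline's tab-separated formats:
# counts.tsv    isoform_id, gene_id, <sample columns>  (TPM scale)
# metadata.tsv  sample_id, sample_type, batch, purity, bias_score,
#               subtype, region
# annotation.tsv  gene_id, kinase_group [, bp_ids (';'-separated)]
# *.gmt         set name, description, tab-separated member genes

#' Read an isoform abundance table
#'
#' Expects a tab-separated file whose header is `isoform_id`, `gene_id`,
#' then one column per sample; one row per isoform. Values are TPM-scale
#' abundances.
#'
#' @param path file path.
#' @return an [isoform_counts] object, row and column order preserved.
#' @export
read_isoform_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 ||
      !identical(colnames(df)[1:2], c("isoform_id", "gene_id")))
    stop("counts file must start with columns 'isoform_id', 'gene_id'")
  if (anyDuplicated(df$isoform_id))
    stop("duplicate isoform id: ",
         df$isoform_id[duplicated(df$isoform_id)][1L])
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[, -(1:2), drop = FALSE], is.numeric, logical(1)))
    stop("non-numeric abundance column: ", names(bad)[1L])
  }
  rownames(vals) <- df$isoform_id
  if (any(vals < 0, na.rm = TRUE)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance at isoform '", rownames(vals)[bad[1L]],
         "', sample '", colnames(vals)[bad[2L]], "'")
  }
  isoform_counts(vals, setNames(df$gene_id, df$isoform_id))
}

#' Write an isoform abundance table
#'
#' @param counts an [isoform_counts] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_isoform_counts <- function(counts, path) {
  df <- data.frame(isoform_id = rownames(counts$values),
                   gene_id = unname(counts$gene_of),
                   counts$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.metadata_cols <- c("sample_id", "sample_type", "batch", "purity",
                    "bias_score", "subtype", "region")

#' Read per-sample metadata
#'
#' Tab-separated, one row per sample with columns `sample_id`,
#' `sample_type` (primary/metastatic), `batch`, `purity` (0-1 or NA),
#' `bias_score` (0-1 or NA), `subtype`, `region`.
#'
#' @param path file path.
#' @return a data.frame with the columns above.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  missing <- setdiff(.metadata_cols, colnames(df))
  if (length(missing))
    stop("metadata file lacks columns: ", paste(missing, collapse = ", "))
  validate_metadata(df)
  df
}

#' Write per-sample metadata
#'
#' @param meta metadata data.frame (see [read_sample_metadata]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  write.table(meta[, .metadata_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  if (!all(meta$sample_type %in% c("primary", "metastatic")))
    stop("sample_type must be 'primary' or 'metastatic'")
  for (col in c("purity", "bias_score")) {
    v <- meta[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("'", col, "' outside [0, 1]")
  }
  invisible(meta)
}

#' Read a kinase-group annotation table
#'
#' Tab-separated with columns `gene_id` and `kinase_group` (one of the
#' phylogenetic kinome groups, with tyrosine kinases subdivided into
#' receptor TK-RTK and non-receptor TK-nRTK), and optionally `bp_ids`, a
#' `;`-separated list of biological-process annotation ids.
#'
#' @param path file path.
#' @return a list with `kinase_group` (named character vector, gene ->
#'   group) and `bp_sets` (named list, gene -> character vector of BP
#'   ids; empty when the column is absent).
#' @export
read_kinome_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!all(c("gene_id", "kinase_group") %in% colnames(df)))
    stop("annotation file needs columns 'gene_id' and 'kinase_group'")
  if (anyDuplicated(df$gene_id))
    stop("gene annotated twice: ", df$gene_id[duplicated(df$gene_id)][1L])
  bp <- list()
  if ("bp_ids" %in% colnames(df))
    bp <- setNames(strsplit(ifelse(is.na(df$bp_ids), "", df$bp_ids), ";",
                            fixed = TRUE),
                   df$gene_id)
  list(kinase_group = setNames(df$kinase_group, df$gene_id), bp_sets = bp)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields set name,
#' description, then member gene ids.
#'
#' @param path file path.
#' @return named list of character vectors (set name -> member genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields")
  setNames(lapply(fields, function(f) unique(f[-(1:2)])),
           vapply(fields, `[[`, character(1), 1L))
}
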