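# Event-level validation of isoform switching from split-read junction
# counts (STAR SJ.out.tab-style coordinates: 1-based, intron-inclusive).

#' Describe a splicing event by its junctions
#'
#' A skipped-exon event carries three junctions (the two inclusion
#' flanks and the skipping junction); two-way events (alternative
#' promoter, mutually exclusive exons, alternative terminal exon) carry
#' two. `favored_direction` states the expected metastatic shift of the
#' event fraction, set by the isoform-quantification result the junction
#' analysis is meant to validate.
#'
#' @param gene_id gene id.
#' @param event_type one of `"skipped_exon"`, `"alt_promoter"`,
#'   `"mutually_exclusive"`, `"alt_terminal"`.
#' @param inclusion_isoforms isoform ids whose proportion drives the
#'   event's \eqn{\psi} (used by the synthetic generator).
#' @param favored_direction `"greater"` or `"less"`: expected direction
#'   of the metastatic event fraction relative to primary.
#' @param anchor integer coordinate offset used to lay the junctions on
#'   a synthetic chromosome; alternatively pass `junctions` explicitly.
#' @param junctions optional data.frame with columns `role`, `chrom`,
#'   `intron_start`, `intron_end`, `strand` overriding the synthetic
#'   layout.
#' @param chrom chromosome name for the synthetic layout.
#' @return list of class `junction_event`.
#' @export
junction_event <- function(gene_id,
                           event_type = c("skipped_exon", "alt_promoter",
                                          "mutually_exclusive",
                                          "alt_terminal"),
                           inclusion_isoforms = character(0),
                           favored_direction = c("greater", "less"),
                           anchor = 10000L, junctions = NULL,
                           chrom = "chrS") {
  event_type <- match.arg(event_type)
  favored_direction <- match.arg(favored_direction)
  if (is.null(junctions)) {
    junctions <- if (event_type == "skipped_exon") {
      data.frame(role = c("flank_left", "flank_right", "skip"),
                 chrom = chrom,
                 intron_start = anchor + c(100L, 300L, 100L),
                 intron_end = anchor + c(200L, 400L, 400L),
                 strand = "+", stringsAsFactors = FALSE)
    } else {
      data.frame(role = c("junction_a", "junction_b"),
                 chrom = chrom,
                 intron_start = anchor + c(100L, 150L),
                 intron_end = anchor + c(400L, 400L),
                 strand = "+", stringsAsFactors = FALSE)
    }
  }
  n_expected <- if (event_type == "skipped_exon") 3L else 2L
  if (nrow(junctions) != n_expected)
    stop(event_type, " events need exactly ", n_expected, " junctions")
  if (any(junctions$intron_start >= junctions$intron_end))
    stop("intron start must be < intron end")
  structure(list(gene_id = gene_id, event_type = event_type,
                 junctions = junctions,
                 inclusion_isoforms = inclusion_isoforms,
                 favored_direction = favored_direction),
            class = "junction_event")
}

#' Event fraction for a skipped exon
#'
#' Inclusion support is the average of the two flanking junction counts;
#' the fraction is the skipping junction's share:
#' `skip / (skip + (flank_left + flank_right) / 2)`. Missing (`NA`) when
#' the denominator is zero — such samples carry no information about the
#' event.
#'
#' @param skip_count,flank_left,flank_right non-negative read counts.
#' @return fraction in \[0, 1\] or `NA`.
#' @export
fraction_skipped_exon <- function(skip_count, flank_left, flank_right) {
  if (any(c(skip_count, flank_left, flank_right) < 0, na.rm = TRUE))
    stop("junction counts must be non-negative")
  inclusion <- (flank_left + flank_right) / 2
  denom <- skip_count + inclusion
  ifelse(denom > 0, skip_count / denom, NA_real_)
}

#' Event fraction for a two-way junction choice
#'
#' Share of reads supporting isoform A's junction:
#' `count_a / (count_a + count_b)`; `NA` when both are zero.
#'
#' @param count_a,count_b non-negative read counts.
#' @return fraction in \[0, 1\] or `NA`.
#' @export
fraction_two_way <- function(count_a, count_b) {
  if (any(c(count_a, count_b) < 0, na.rm = TRUE))
    stop("junction counts must be non-negative")
  denom <- count_a + count_b
  ifelse(denom > 0, count_a / denom, NA_real_)
}

junction_key <- function(chrom, start, end, strand) {
  paste(chrom, start, end, strand, sep = ":")
}

# per-sample counts for one junction role; samples absent from the
# table (STAR omits zero-read junctions) count as 0
role_counts <- function(event, table, role, sample_ids) {
  j <- event$junctions[event$junctions$role == role, ]
  key <- junction_key(table$chrom, table$intron_start, table$intron_end,
                      table$strand)
  hit <- key == junction_key(j$chrom, j$intron_start, j$intron_end,
                             j$strand)
  out <- setNames(rep(0L, length(sample_ids)), sample_ids)
  sub <- table[hit & table$sample_id %in% sample_ids, ]
  out[sub$sample_id] <- sub$unique_read_count
  out
}

#' Group comparison of a splicing event's junction fractions
#'
#' Computes the event-appropriate per-sample fraction and compares the
#' metastatic against the primary group with a one-sided Wilcoxon
#' rank-sum test in the event's favored direction. Samples with a
#' missing fraction (no reads over the event) are dropped and counted.
#'
#' @param event a [junction_event] whose junctions appear in `table`.
#' @param table junction count table (see [generate_junction_counts] or
#'   [read_junction_counts]).
#' @param meta metadata data.frame with `sample_id` and `sample_type`.
#' @return list with `p` (one-sided), `fractions` (named per-sample),
#'   `group_medians`, `n_primary`, `n_metastatic` and `n_dropped`.
#' @export
junction_group_test <- function(event, table, meta) {
  key_all <- junction_key(table$chrom, table$intron_start,
                          table$intron_end, table$strand)
  want <- junction_key(event$junctions$chrom, event$junctions$intron_start,
                       event$junctions$intron_end, event$junctions$strand)
  if (!all(want %in% key_all))
    stop("event junctions absent from the table: ",
         paste(setdiff(want, key_all), collapse = ", "))
  sample_ids <- meta$sample_id
  frac <- if (event$event_type == "skipped_exon") {
    fraction_skipped_exon(role_counts(event, table, "skip", sample_ids),
                          role_counts(event, table, "flank_left",
                                      sample_ids),
                          role_counts(event, table, "flank_right",
                                      sample_ids))
  } else {
    fraction_two_way(role_counts(event, table, "junction_a", sample_ids),
                     role_counts(event, table, "junction_b", sample_ids))
  }
  names(frac) <- sample_ids
  ok <- !is.na(frac)
  type <- setNames(meta$sample_type, meta$sample_id)
  met <- frac[ok & type[sample_ids] == "metastatic"]
  pri <- frac[ok & type[sample_ids] == "primary"]
  if (length(met) < 2 || length(pri) < 2)
    stop("untestable event: a group has < 2 samples with reads")
  p <- rank_sum_pvalue(met, pri, alternative = event$favored_direction)
  list(p = p, fractions = frac,
       group_medians = c(primary = median(pri), metastatic = median(met)),
       n_primary = length(pri), n_metastatic = length(met),
       n_dropped = sum(!ok))
}

#' Read/write junction count tables
#'
#' Six-column tab-separated dialect following the STAR `SJ.out.tab`
#' coordinate convention (1-based, intron-inclusive): `chrom`,
#' `intron_start`, `intron_end`, `strand`, `sample_id`,
#' `unique_read_count`.
#'
#' @param path file path.
#' @return data.frame with the columns above.
#' @export
read_junction_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "intron_start", "intron_end", "strand", "sample_id",
            "unique_read_count")
  if (!all(need %in% colnames(df)))
    stop("junction file lacks columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  if (any(df$unique_read_count < 0) ||
      any(df$unique_read_count != round(df$unique_read_count)))
    stop("junction read counts must be non-negative integers")
  df[need]
}

#' @rdname read_junction_counts
#' @param table junction count data.frame.
#' @export
write_junction_counts <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write junction event definitions
#'
#' Flat tab-separated format, one row per junction: `gene_id`,
#' `event_type`, `role`, `chrom`, `intron_start`, `intron_end`,
#' `strand`, `favored_direction`.
#'
#' @param path file path.
#' @return named list of [junction_event]s (gene id -> event).
#' @export
read_junction_events <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$gene_id), function(d) {
    junction_event(d$gene_id[1L], d$event_type[1L],
                   favored_direction = d$favored_direction[1L],
                   junctions = data.frame(role = d$role, chrom = d$chrom,
                                          intron_start = d$intron_start,
                                          intron_end = d$intron_end,
                                          strand = d$strand,
                                          stringsAsFactors = FALSE))
  })
  out
}

#' @rdname read_junction_events
#' @param events named list of [junction_event]s.
#' @export
write_junction_events <- function(events, path) {
  rows <- lapply(events, function(ev)
    data.frame(gene_id = ev$gene_id, event_type = ev$event_type,
               ev$junctions, favored_direction = ev$favored_direction,
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[, c("gene_id", "event_type", "role", "chrom", "intron_start",
               "intron_end", "strand", "favored_direction")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
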