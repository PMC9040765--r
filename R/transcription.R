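#' @title Transcript-abundance aggregation per gene group and phylum
#'
#' @description
#' Metatranscriptome TPM values (transcripts per million, pseudoaligned to
#' the sulfur-cycling genes predicted from the genomes) are summed over
#' named gene groups (e.g. the Asr system, the Dsr system) and attributed
#' to phyla via the genome taxonomy; per-sample tables and a pooled view
#' are produced.
#'
#' @name transcription
NULL

#' Read a transcript-abundance TSV
#'
#' Expected columns: `sample_id`, `genome_id`, `gene_symbol`, `tpm`.
#' TPM values must be non-negative and (sample, genome, gene) triples
#' unique after load.
#'
#' @param path file path.
#' @return validated data frame.
#' @export
read_tpm_table <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "genome_id", "gene_symbol",
                                "tpm"))
  validate_tpm_table(df)
}

#' Validate an in-memory transcript-abundance table
#' @param df data frame with the columns of [read_tpm_table()].
#' @return the validated data frame.
#' @export
validate_tpm_table <- function(df) {
  stopifnot(is.data.frame(df))
  df$tpm <- suppressWarnings(as.numeric(df$tpm))
  if (anyNA(df$tpm) || any(df$tpm < 0)) {
    stop("tpm values must be non-negative numbers", call. = FALSE)
  }
  key <- paste(df$sample_id, df$genome_id, df$gene_symbol, sep = "\t")
  if (anyDuplicated(key)) {
    stop("duplicate (sample, genome, gene) rows in abundance table",
         call. = FALSE)
  }
  df
}

#' Default sulfur gene groups for expression aggregation
#'
#' Groups mirror the functional systems of the capability rules: the Asr
#' and Dsr sulfite-reduction systems, sulfate-reduction genes
#' (Sat + AprAB + QmoABC), thiosulfate/polysulfide/tetrathionate reduction,
#' rhodanese, and the sulfurhydrogenases.
#'
#' @return named list `group name -> gene symbol vector`.
#' @export
default_gene_groups <- function() {
  list(
    asr_system = c("AsrA", "AsrB", "AsrC"),
    dsr_system = c("DsrA", "DsrB", "DsrC", "DsrK", "DsrM", "DsrJ",
                   "DsrO", "DsrP", "DsrD"),
    sulfate_reduction_genes = c("Sat", "AprA", "AprB",
                                "QmoA", "QmoB", "QmoC"),
    phs_system = c("PhsA", "PhsB", "PhsC"),
    psr_system = c("PsrA", "PsrB", "PsrC"),
    tetrathionate_reduction_genes = c("Otr", "TtrA", "TtrB", "TtrC"),
    rhodanese = "Rhd",
    sulfurhydrogenases = c("HydA", "HydB", "HydC", "HydD",
                           "ShyA", "ShyB", "ShyC", "ShyD")
  )
}

#' Aggregate TPM per gene group and phylum
#'
#' Every abundance row is assigned to the first group whose gene set
#' contains its symbol (shipped groups are disjoint); symbols in no group
#' go to an explicit `"unassigned"` bucket, never dropped. Sums are
#' attributed to the phylum of the contributing genome. Conservation
#' holds per sample: the group totals (including unassigned) sum to the
#' input TPM total.
#'
#' @param abundances validated abundance table (see [read_tpm_table()]).
#' @param gene_groups named list `group -> gene symbols`
#'   (default [default_gene_groups()]).
#' @param genomes a genome collection data frame supplying `phylum` per
#'   `genome_id`.
#' @return list with `by_phylum` (long data frame: sample_id, group,
#'   phylum, tpm_sum), `group_totals` (sample_id, group, tpm_sum) and
#'   `pooled_group_totals` (group, tpm_sum; summed across samples).
#' @export
aggregate_tpm <- function(abundances, gene_groups = default_gene_groups(),
                          genomes) {
  abundances <- validate_tpm_table(abundances)
  unknown <- setdiff(unique(abundances$genome_id), genomes$genome_id)
  if (length(unknown) > 0L) {
    stop("abundance table references unknown genome id(s): ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  sym2group <- rep(names(gene_groups),
                   vapply(gene_groups, length, integer(1)))
  names(sym2group) <- unlist(gene_groups, use.names = FALSE)
  grp <- unname(sym2group[abundances$gene_symbol])
  grp[is.na(grp)] <- "unassigned"
  phylum <- genomes$phylum[match(abundances$genome_id, genomes$genome_id)]

  agg <- stats::aggregate(
    list(tpm_sum = abundances$tpm),
    by = list(sample_id = abundances$sample_id, group = grp,
              phylum = phylum),
    FUN = sum)
  agg <- agg[order(agg$sample_id, agg$group, agg$phylum), , drop = FALSE]
  rownames(agg) <- NULL

  gt <- stats::aggregate(
    list(tpm_sum = agg$tpm_sum),
    by = list(sample_id = agg$sample_id, group = agg$group), FUN = sum)
  gt <- gt[order(gt$sample_id, gt$group), , drop = FALSE]
  rownames(gt) <- NULL

  pooled <- stats::aggregate(
    list(tpm_sum = gt$tpm_sum), by = list(group = gt$group), FUN = sum)
  pooled <- pooled[order(pooled$group), , drop = FALSE]
  rownames(pooled) <- NULL

  list(by_phylum = agg, group_totals = gt, pooled_group_totals = pooled)
}

#' Ratio of summed TPM between two gene groups
#'
#' @param aggregated output of [aggregate_tpm()].
#' @param group_a,group_b group names (numerator, denominator).
#' @param sample a sample id, or `NULL` (default) for the pooled view
#'   (summing across samples before taking the ratio).
#' @return the ratio; `NA` with a `"reason"` attribute when the
#'   denominator total is zero or the group is absent.
#' @export
expression_ratio <- function(aggregated, group_a, group_b, sample = NULL) {
  tab <- if (is.null(sample)) {
    aggregated$pooled_group_totals
  } else {
    gt <- aggregated$group_totals
    gt[gt$sample_id == sample, c("group", "tpm_sum"), drop = FALSE]
  }
  tot <- function(g) sum(tab$tpm_sum[tab$group == g])
  a <- tot(group_a)
  b <- tot(group_b)
  if (b <= 0) {
    return(structure(NA_real_, reason = "undefined ratio: zero denominator"))
  }
  a / b
}
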